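#' Build a suitability factor layer
#'
#' A factor layer is one gridded criterion of the construction-land
#' suitability analysis (e.g. land cover, fracture zone, mean gradient,
#' soil property): a matrix of non-negative grade scores plus a weight.
#' A grade of 0 marks a cell forbidden for that factor; `NA` marks
#' no-data. All layers of one analysis must share shape and no-data mask.
#'
#' @param grid numeric matrix of grade scores (`NA` = no-data, 0 =
#'   forbidden, otherwise conventionally on \{1, 3, 5\}).
#' @param weight factor weight in (0, 1]; weights across layers must sum
#'   to 1.
#' @param name layer name.
#' @return an object of class `cc_layer`.
#' @export
cc_layer <- function(grid, weight, name = "factor") {
  stopifnot(is.matrix(grid), is.numeric(grid),
            is.numeric(weight), length(weight) == 1L,
            weight > 0, weight <= 1,
            is.character(name), length(name) == 1L)
  if (any(grid < 0, na.rm = TRUE)) {
    stop("layer [", name, "]: negative grade scores are not allowed",
         call. = FALSE)
  }
  structure(list(name = name, weight = as.numeric(weight),
                 grid = grid), class = "cc_layer")
}

#' Weighted multi-factor suitability scores
#'
#' Overlays aligned factor layers into a per-cell comprehensive
#' suitability score: the weighted sum \eqn{\sum_j W_j C_{ij}} of the
#' grade scores, except that any factor grading a cell 0 vetoes it (the
#' score is 0 regardless of the other factors), and no-data cells stay
#' `NA`. Weights must sum to 1.
#'
#' @param layers list of [cc_layer()] objects sharing shape and no-data
#'   mask.
#' @return numeric matrix of scores.
#' @examples
#' a <- cc_layer(matrix(c(4, 0), 1), 0.5, "cover")
#' b <- cc_layer(matrix(c(2, 5), 1), 0.5, "slope")
#' score_cells(list(a, b))  # 3 and 0 (vetoed)
#' @export
score_cells <- function(layers) {
  if (inherits(layers, "cc_layer")) layers <- list(layers)
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "cc_layer")))
  w <- vapply(layers, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("land_suitability.weights: weights sum to ", sum(w),
         ", must sum to 1", call. = FALSE)
  }
  dims <- lapply(layers, function(l) dim(l$grid))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("factor layers have mismatched shapes", call. = FALSE)
  }
  masks <- lapply(layers, function(l) is.na(l$grid))
  for (m in masks[-1]) {
    if (!identical(m, masks[[1]])) {
      stop("factor layers have mismatched no-data masks", call. = FALSE)
    }
  }
  score <- matrix(0, nrow(layers[[1]]$grid), ncol(layers[[1]]$grid))
  veto <- matrix(FALSE, nrow(score), ncol(score))
  for (k in seq_along(layers)) {
    g <- layers[[k]]$grid
    veto <- veto | (!is.na(g) & g == 0)
    score <- score + w[k] * ifelse(is.na(g), 0, g)
  }
  score[veto] <- 0
  score[masks[[1]]] <- NA_real_
  score
}

#' Four-level suitability classification
#'
#' Classifies comprehensive scores into `"forbidden"` (score 0),
#' `"limited"` (below `thresholds[1]`), `"less-suitable"` (between the
#' thresholds) and `"suitable"` (at or above `thresholds[2]`).
#'
#' @param scores numeric matrix from [score_cells()].
#' @param thresholds two strictly ascending positive class cut points
#'   `(t1, t2)`; default `c(2, 4)` for grades on \{0, 1, 3, 5\}.
#' @return character matrix over the four class labels (`NA` kept).
#' @export
classify_suitability <- function(scores, thresholds = c(2, 4)) {
  stopifnot(is.numeric(scores), is.numeric(thresholds),
            length(thresholds) == 2L)
  t1 <- thresholds[1]; t2 <- thresholds[2]
  if (!(0 < t1 && t1 < t2)) {
    stop("thresholds must satisfy 0 < t1 < t2", call. = FALSE)
  }
  cls <- matrix(NA_character_, nrow(scores), ncol(scores))
  cls[!is.na(scores) & scores == 0] <- "forbidden"
  cls[!is.na(scores) & scores > 0 & scores < t1] <- "limited"
  cls[!is.na(scores) & scores >= t1 & scores < t2] <- "less-suitable"
  cls[!is.na(scores) & scores >= t2] <- "suitable"
  cls
}

#' Suitable construction-land area
#'
#' Counts the cells classified `"less-suitable"` or `"suitable"` and
#' multiplies by the cell area. This area is the support value of the
#' land-resource indicator (the matching pressure is the developed
#' construction-land area).
#'
#' @param classes character matrix from [classify_suitability()].
#' @param cell_area area of one cell in square metres.
#' @return area in square metres.
#' @export
suitable_area <- function(classes, cell_area) {
  stopifnot(is.character(classes), is.numeric(cell_area),
            length(cell_area) == 1L, cell_area > 0)
  known <- c("forbidden", "limited", "less-suitable", "suitable")
  if (!all(classes[!is.na(classes)] %in% known)) {
    stop("grid is not classified; run classify_suitability() first",
         call. = FALSE)
  }
  cell_area * sum(classes %in% c("less-suitable", "suitable"))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' row-major cell values, origin upper-left. No-data cells become `NA`.
#'
#' @param path file path.
#' @return numeric matrix with attributes `xllcorner`, `yllcorner`,
#'   `cellsize` and `nodata`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list(nodata = -9999)
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    key <- tolower(kv[1])
    key <- switch(key, nodata_value = "nodata", key)
    hdr[[key]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, ": missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid ", path, ": expected ", hdr$ncols * hdr$nrows,
         " cells, found ", length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata] <- NA_real_
  structure(m, xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
            cellsize = hdr$cellsize, nodata = hdr$nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_asc()]; `NA` cells are written as the no-data value.
#' Values round-trip exactly (written with full double precision).
#'
#' @param grid numeric matrix, row-major with origin upper-left.
#' @param path output file path.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell edge length (square cells).
#' @param nodata no-data marker written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, xllcorner = 0, yllcorner = 0,
                      cellsize = attr(grid, "cellsize"),
                      nodata = -9999) {
  stopifnot(is.matrix(grid), is.numeric(grid))
  if (is.null(cellsize)) cellsize <- 1
  if (!is.null(attr(grid, "xllcorner")) && missing(xllcorner)) {
    xllcorner <- attr(grid, "xllcorner")
  }
  if (!is.null(attr(grid, "yllcorner")) && missing(yllcorner)) {
    yllcorner <- attr(grid, "yllcorner")
  }
  num <- function(x) formatC(x, format = "g", digits = 17)
  hdr <- c(paste("ncols", ncol(grid)),
           paste("nrows", nrow(grid)),
           paste("xllcorner", num(xllcorner)),
           paste("yllcorner", num(yllcorner)),
           paste("cellsize", num(cellsize)),
           paste("NODATA_value", num(nodata)))
  g <- grid
  g[is.na(g)] <- nodata
  body <- apply(g, 1, function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
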