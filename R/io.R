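#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing the indicator tree and the
#' estimator settings, validates it against the schema, and returns it
#' as a `cc_config` object. Validation is exhaustive: every violation is
#' collected (unknown keys, missing fields, bad values, weight sums) and
#' reported in a single error naming each offending location.
#'
#' Schema (top level): `name`, `warning_width`, `dimensions` (each with
#' `id`, `name`, `mode`, `weight`, `factors`; factors with `id`, `name`,
#' `weight`, `indicators`; indicators with `id`, `name`, `units`,
#' `pressure`, `support`, `weight`, `computed_by`), `land_suitability`
#' (`weights`, `thresholds`), `lai_table`, `pollutant_combine`, `seed`,
#' `output`.
#'
#' @param path path to a YAML configuration file.
#' @return a validated `cc_config` list.
#' @seealso [save_config()], [config_to_tree()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  errs <- validate_config(cfg)
  if (length(errs)) {
    stop("invalid configuration ", path, ":\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "cc_config")
}

#' Save a run configuration
#'
#' @param config a `cc_config` (or plain list with the same schema).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, paste0(...))
  known_top <- c("name", "warning_width", "dimensions", "land_suitability",
                 "lai_table", "pollutant_combine", "seed", "output")
  if (!is.list(cfg)) return("config root must be a mapping")
  for (k in setdiff(names(cfg), known_top)) say("unknown key: ", k)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!is.null(cfg$warning_width) &&
      (!num1(cfg$warning_width) || cfg$warning_width < 0 ||
       cfg$warning_width >= 1)) {
    say("warning_width: must be a number in [0, 1)")
  }
  if (is.null(cfg$dimensions) || !length(cfg$dimensions)) {
    say("dimensions: at least one dimension is required")
  } else {
    for (i in seq_along(cfg$dimensions)) {
      dm <- cfg$dimensions[[i]]
      dpath <- paste0("dimensions[", i, "]")
      for (k in setdiff(names(dm), c("id", "name", "mode", "weight",
                                     "factors"))) {
        say(dpath, ": unknown key: ", k)
      }
      if (is.null(dm$id)) say(dpath, ": missing id")
      if (!is.null(dm$mode) && !dm$mode %in% c("flat", "nested")) {
        say(dpath, ".mode: must be 'flat' or 'nested'")
      }
      if (is.null(dm$factors) || !length(dm$factors)) {
        say(dpath, ": at least one factor is required")
        next
      }
      for (j in seq_along(dm$factors)) {
        fc <- dm$factors[[j]]
        fpath <- paste0(dpath, ".factors[", j, "]")
        for (k in setdiff(names(fc), c("id", "name", "weight",
                                       "indicators"))) {
          say(fpath, ": unknown key: ", k)
        }
        if (is.null(fc$id)) say(fpath, ": missing id")
        if (is.null(fc$indicators) || !length(fc$indicators)) {
          say(fpath, ": at least one indicator is required")
          next
        }
        for (l in seq_along(fc$indicators)) {
          ind <- fc$indicators[[l]]
          ipath <- paste0(fpath, ".indicators[", l, "]")
          for (k in setdiff(names(ind), c("id", "name", "units",
                                          "pressure", "support", "weight",
                                          "computed_by"))) {
            say(ipath, ": unknown key: ", k)
          }
          if (is.null(ind$id)) say(ipath, ": missing id")
          if (!num1(ind$pressure %||% NA) || ind$pressure < 0) {
            say(ipath, ".pressure: must be a non-negative number")
          }
          if (!num1(ind$support %||% NA) || ind$support <= 0) {
            say(ipath, ".support: must be a positive number")
          }
        }
      }
    }
  }
  ls <- cfg$land_suitability
  if (!is.null(ls)) {
    for (k in setdiff(names(ls), c("weights", "thresholds"))) {
      say("land_suitability: unknown key: ", k)
    }
    if (!is.null(ls$weights) &&
        abs(sum(unlist(ls$weights)) - 1) > 1e-9) {
      say("land_suitability.weights: must sum to 1 (got ",
          sum(unlist(ls$weights)), ")")
    }
    th <- unlist(ls$thresholds)
    if (!is.null(th) && (length(th) != 2L || !(0 < th[1] && th[1] < th[2]))) {
      say("land_suitability.thresholds: need two ascending positive values")
    }
  }
  if (!is.null(cfg$pollutant_combine) &&
      !cfg$pollutant_combine %in% c("min", "rms")) {
    say("pollutant_combine: must be 'min' or 'rms'")
  }
  errs
}

#' Build an assessment tree from a configuration
#'
#' @param config a `cc_config` from [load_config()].
#' @return a [cc_tree()].
#' @export
config_to_tree <- function(config) {
  dims <- lapply(config$dimensions, function(dm) {
    facs <- lapply(dm$factors, function(fc) {
      inds <- lapply(fc$indicators, function(ind) {
        cc_indicator(ind$id, pressure = ind$pressure,
                     support = ind$support,
                     name = ind$name %||% ind$id,
                     units = ind$units %||% "",
                     weight = ind$weight %||% 1)
      })
      do.call(cc_factor, c(list(fc$id), inds,
                           list(name = fc$name %||% fc$id,
                                weight = fc$weight %||% 1)))
    })
    do.call(cc_dimension, c(list(dm$id), facs,
                            list(name = dm$name %||% dm$id,
                                 mode = dm$mode %||% "flat",
                                 weight = dm$weight %||% 1)))
  })
  do.call(cc_tree, c(dims, list(name = config$name %||% "CORE-CC")))
}

#' Render an assessment report to files
#'
#' Writes the fitted assessment in up to three forms: `report.csv` (one
#' row per tree node with the display rounding of the classic results
#' table — ratio to two decimals, degree as whole percent), a
#' full-precision machine-readable `report.json`, and a plain-text
#' `report.txt` summary that names the most binding (lowest-ratio)
#' indicator of every dimension.
#'
#' @param fit a [corecc()] result.
#' @param dir output directory, created if needed.
#' @param formats subset of `c("csv", "json", "text")`.
#' @return named character vector of the files written, invisibly.
#' @export
render_report <- function(fit, dir, formats = c("csv", "json", "text")) {
  stopifnot(inherits(fit, "corecc"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  rep <- fit$report
  if ("csv" %in% formats) {
    f <- file.path(dir, "report.csv")
    utils::write.csv(
      data.frame(path = rep$path, level = rep$level, name = rep$name,
                 surplus_ratio = sprintf("%.2f", rep$ratio),
                 state = rep$state, degree = round(rep$degree),
                 stringsAsFactors = FALSE),
      f, row.names = FALSE)
    out["csv"] <- f
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(name = fit$tree$name, timestamp = fit$timestamp,
           warning_width = fit$warning_width,
           overall = list(ratio = fit$overall,
                          state = classify_state(fit$overall,
                                                 fit$warning_width)),
           nodes = rep),
      f, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out["json"] <- f
  }
  if ("text" %in% formats) {
    f <- file.path(dir, "report.txt")
    s <- summary(fit)
    txt <- c(sprintf("Carrying-capacity assessment: %s", fit$tree$name),
             sprintf("Overall: ratio %.4f, state %s, degree %d%%",
                     fit$overall,
                     classify_state(fit$overall, fit$warning_width),
                     round(abs(fit$overall) * 100)),
             "",
             "Dimensions (most binding indicator):")
    dd <- rep[rep$level == "dimension", , drop = FALSE]
    for (i in seq_len(nrow(dd))) {
      b <- s$binding[s$binding$dimension == dd$id[i], , drop = FALSE]
      txt <- c(txt, sprintf("  %s: ratio %.4f (%s); binding: %s (%.2f)",
                            dd$name[i], dd$ratio[i], dd$state[i],
                            b$name[1], b$ratio[1]))
    }
    writeLines(txt, f)
    out["text"] <- f
  }
  invisible(out)
}

log_msg <- function(level, module, ...) {
  message(sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, module, paste0(...)))
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

cli_usage <- function() {
  c("usage: corecc <subcommand> [--flags]",
    "",
    "subcommands:",
    "  assess      --config FILE --out DIR [--warning-width W] [--format csv,json,text]",
    "  suitability --rasters A.asc,B.asc,... [--weights w1,w2,...]",
    "              [--thresholds t1,t2] [--cellsize S]",
    "  tmdl        --matrix P.csv --limits L.csv --bounds B.csv",
    "  lai         --composition C.csv",
    "  survey      [--point-intercept PIT.csv] [--belt BELT.csv]",
    "  synth       --out DIR [--seed N]")
}

num_list <- function(x) as.numeric(strsplit(as.character(x), ",")[[1]])

#' Command-line entry point
#'
#' Dispatches the package's subcommands: `assess` (config to report
#' files), `suitability` (factor rasters to suitable area), `tmdl`
#' (response-field CSVs to assimilative capacity), `lai` (land-cover
#' composition to Sum LAI), `survey` (transect CSVs to coverage and
#' density) and `synth` (synthetic inputs written to a directory).
#' Results go to stdout or files; log lines go to stderr.
#'
#' A thin wrapper script calling this function is installed under
#' `system.file("scripts", "corecc.R", package = "corecc")`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code: 0 success, 1 runtime error, 2 usage or
#'   validation error.
#' @export
corecc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    writeLines(cli_usage())
    return(if (length(args)) 0L else 2L)
  }
  sub <- args[1]
  flags <- tryCatch(parse_flags(args[-1]),
                    error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    writeLines(cli_usage())
    return(2L)
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
             validation = function(e) { message("error: ", conditionMessage(e)); 2L },
             error = function(e) { message("error: ", conditionMessage(e)); 1L })
  }
  switch(
    sub,
    assess = {
      if (is.null(flags$config) || is.null(flags$out)) {
        message("assess requires --config and --out"); return(2L)
      }
      cfg <- tryCatch(load_config(flags$config), error = function(e) e)
      if (inherits(cfg, "error")) {
        message(conditionMessage(cfg)); return(2L)
      }
      run({
        log_msg("INFO", "assess", "config: ", flags$config)
        width <- as.numeric(flags$`warning-width` %||%
                              cfg$warning_width %||% 0.10)
        fit <- corecc(config_to_tree(cfg), warning_width = width)
        fmts <- strsplit(flags$format %||% "csv,json,text", ",")[[1]]
        files <- render_report(fit, flags$out, fmts)
        log_msg("INFO", "assess", "wrote: ",
                paste(files, collapse = ", "))
        cat(sprintf("overall %.4f (%s)\n", fit$overall,
                    classify_state(fit$overall, width)))
      })
    },
    suitability = {
      if (is.null(flags$rasters)) {
        message("suitability requires --rasters"); return(2L)
      }
      run({
        paths <- strsplit(flags$rasters, ",")[[1]]
        grids <- lapply(paths, read_asc)
        w <- if (is.null(flags$weights)) {
          rep(1 / length(grids), length(grids))
        } else num_list(flags$weights)
        layers <- Map(function(g, wt, nm) cc_layer(unclass_grid(g), wt, nm),
                      grids, w, basename(paths))
        th <- if (is.null(flags$thresholds)) c(2, 4)
              else num_list(flags$thresholds)
        cs <- as.numeric(flags$cellsize %||%
                           attr(grids[[1]], "cellsize") %||% 1)
        cls <- classify_suitability(score_cells(layers), th)
        cat(sprintf("suitable_area_m2 %.6g\n", suitable_area(cls, cs^2)))
      })
    },
    tmdl = {
      if (is.null(flags$matrix) || is.null(flags$limits) ||
          is.null(flags$bounds)) {
        message("tmdl requires --matrix, --limits and --bounds")
        return(2L)
      }
      run({
        P <- as.matrix(utils::read.csv(flags$matrix, row.names = 1,
                                       check.names = FALSE))
        lim <- utils::read.csv(flags$limits)
        bnd <- utils::read.csv(flags$bounds)
        res <- solve_capacity(P, limits = lim$limit,
                              lower = bnd$lower, upper = bnd$upper,
                              background = lim$background %||% 0)
        if (res$status != "optimal") {
          stop("infeasible: standards violated in ",
               paste(res$violated, collapse = ", "), call. = FALSE)
        }
        cat(sprintf("capacity_t_per_a %.6g\n", res$capacity))
      })
    },
    lai = {
      if (is.null(flags$composition)) {
        message("lai requires --composition"); return(2L)
      }
      run({
        comp <- utils::read.csv(flags$composition)
        areas <- stats::setNames(comp$area, comp$type)
        cat(sprintf("sum_lai %.6g\n", sum_lai(areas)))
      })
    },
    survey = {
      if (is.null(flags$`point-intercept`) && is.null(flags$belt)) {
        message("survey requires --point-intercept and/or --belt")
        return(2L)
      }
      run({
        if (!is.null(flags$`point-intercept`)) {
          pit <- utils::read.csv(flags$`point-intercept`)
          cov <- pool_transects(hard_coral_coverage(pit$n, pit$M))
          cat(sprintf("hard_coral_coverage_pct %.6g\n", cov))
        }
        if (!is.null(flags$belt)) {
          belt <- utils::read.csv(flags$belt)
          den <- pool_transects(fish_density(belt$N, belt$L, belt$W))
          cat(sprintf("fish_density_per_m2 %.6g\n", den))
        }
      })
    },
    synth = {
      if (is.null(flags$out)) {
        message("synth requires --out"); return(2L)
      }
      run({
        seed <- as.integer(flags$seed %||% 1L)
        log_msg("INFO", "synth", "seed: ", seed)
        dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
        isl <- make_island(seed = seed)
        for (l in isl$layers) {
          write_asc(l$grid,
                    file.path(flags$out,
                              paste0(gsub(" ", "_", l$name), ".asc")),
                    cellsize = isl$cellsize)
        }
        utils::write.csv(data.frame(type = names(isl$composition),
                                    area = unname(isl$composition)),
                         file.path(flags$out, "land_cover.csv"),
                         row.names = FALSE)
        utils::write.csv(simulate_point_intercept(0.3, seed = seed),
                         file.path(flags$out, "point_intercept.csv"),
                         row.names = FALSE)
        utils::write.csv(simulate_belt(0.2, seed = seed),
                         file.path(flags$out, "belt.csv"),
                         row.names = FALSE)
        rf <- make_response_field(seed = seed)
        utils::write.csv(as.data.frame(rf$P),
                         file.path(flags$out, "response_field.csv"))
        utils::write.csv(data.frame(area = rownames(rf$P),
                                    limit = rf$limits),
                         file.path(flags$out, "limits.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(source = colnames(rf$P),
                                    lower = rf$lower, upper = rf$upper),
                         file.path(flags$out, "bounds.csv"),
                         row.names = FALSE)
        log_msg("INFO", "synth", "wrote inputs to ", flags$out)
      })
    },
    {
      message("unknown subcommand: ", sub)
      writeLines(cli_usage())
      2L
    })
}

unclass_grid <- function(g) {
  attributes(g) <- attributes(g)["dim"]
  g
}
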