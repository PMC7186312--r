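# Post-processing: fiber filtering by property thresholds and
# combination of per-image outputs into dataset-level tables.

#' Build a fiber filter
#'
#' Each of the four fiber properties (`length`, `width`, `straightness`,
#' `angle_deg`) may carry one criterion; criteria combine by AND. Kinds:
#' * `absolute(min, max)` — keep values in `[min, max]` (either open end
#'   may be omitted);
#' * `percentage(lower, upper)` — keep values between the lower and upper
#'   inclusive percentiles (linear-interpolation quantiles) of the
#'   per-image distribution;
#' * `top_n(n)` / `bottom_n(n)` — keep the n largest / smallest values
#'   (ties broken by fiber id).
#'
#' @param ... named criteria, e.g.
#'   `length = list(kind = "top_n", n = 10)` or
#'   `width = list(kind = "absolute", min = 8)`.
#' @return an object of class `fiber_filter`.
#' @export
fiber_filter <- function(...) {
  crit <- list(...)
  props <- c("length", "width", "straightness", "angle_deg")
  bad <- setdiff(names(crit), props)
  if (length(bad) > 0) stop("unknown fiber property: ",
                            paste(bad, collapse = ", "))
  for (nm in names(crit)) {
    cr <- crit[[nm]]
    kind <- cr$kind
    if (!kind %in% c("absolute", "percentage", "top_n", "bottom_n")) {
      stop("unknown criterion kind: ", kind)
    }
    if (kind %in% c("top_n", "bottom_n") && (is.null(cr$n) || cr$n < 1)) {
      stop(kind, " requires n >= 1")
    }
    if (kind == "percentage") {
      lo <- if (is.null(cr$lower)) 0 else cr$lower
      hi <- if (is.null(cr$upper)) 100 else cr$upper
      if (lo < 0 || hi > 100 || lo > hi) stop("invalid percentage bounds")
    }
    if (kind == "absolute" && !is.null(cr$min) && !is.null(cr$max) &&
        cr$min > cr$max) {
      stop("absolute criterion requires min <= max")
    }
  }
  structure(crit, class = "fiber_filter")
}

#' Filter a fiber table
#'
#' Applies a [fiber_filter()] to a per-image fiber table; an empty filter
#' is the identity (useful for pure output combination).
#'
#' @param fibers fiber data frame with columns `id`, `length`, `width`,
#'   `straightness`, `angle_deg`.
#' @param filter a [fiber_filter()].
#' @return the filtered fiber table.
#' @export
filter_fibers <- function(fibers, filter = fiber_filter()) {
  if (!inherits(filter, "fiber_filter")) {
    stop("filter must be built with fiber_filter()")
  }
  keep <- rep(TRUE, nrow(fibers))
  for (nm in names(filter)) {
    cr <- filter[[nm]]
    v <- fibers[[nm]]
    k <- switch(cr$kind,
      absolute = {
        ok <- rep(TRUE, length(v))
        if (!is.null(cr$min)) ok <- ok & v >= cr$min
        if (!is.null(cr$max)) ok <- ok & v <= cr$max
        ok
      },
      percentage = {
        lo <- if (is.null(cr$lower)) 0 else cr$lower
        hi <- if (is.null(cr$upper)) 100 else cr$upper
        q <- stats::quantile(v, c(lo, hi) / 100, type = 7, names = FALSE)
        v >= q[1] & v <= q[2]
      },
      top_n = {
        ord <- order(-v, fibers$id)
        seq_along(v) %in% ord[seq_len(min(cr$n, length(v)))]
      },
      bottom_n = {
        ord <- order(v, fibers$id)
        seq_along(v) %in% ord[seq_len(min(cr$n, length(v)))]
      })
    keep <- keep & k
  }
  fibers[keep, , drop = FALSE]
}

# Histogram mode with Freedman-Diaconis bins (ties -> lowest bin).
.fd_mode <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  if (length(unique(v)) == 1) return(v[1])
  h <- graphics::hist(v, breaks = "FD", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Combine per-image output tables
#'
#' Reads every `*_fibers.csv` (or `*_features.csv`) table in a folder,
#' binds them with an `image` column (ordered by image name), and builds
#' a per-image summary with median, mode, mean, variance, standard
#' deviation, minimum and maximum of each numeric property. Missing or
#' malformed files are reported: malformed CSVs raise an error naming the
#' file; an empty folder yields empty outputs with a warning.
#'
#' @param folder directory containing per-image CSV outputs.
#' @param pattern filename pattern of the per-image tables.
#' @param properties columns to summarize (default: all numeric except
#'   ids).
#' @return list with `combined` and `summary` data frames.
#' @export
combine_outputs <- function(folder, pattern = "_fibers\\.csv$",
                            properties = NULL) {
  files <- sort(list.files(folder, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) {
    warning("no per-image tables found in ", folder)
    return(list(combined = data.frame(), summary = data.frame()))
  }
  tabs <- lapply(files, function(f) {
    d <- tryCatch(utils::read.csv(f, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed CSV: ", f, " (",
                                           conditionMessage(e), ")"))
    d$image <- sub(pattern, "", basename(f))
    d
  })
  combined <- do.call(rbind, tabs)
  combined <- combined[, c("image", setdiff(names(combined), "image"))]
  if (is.null(properties)) {
    properties <- setdiff(names(combined)[vapply(combined, is.numeric,
                                                 logical(1))],
                          c("id", "fiber", "vertex", "group", "n_vertices"))
  }
  summ <- do.call(rbind, lapply(split(combined, combined$image),
                                function(d) {
    rows <- lapply(properties, function(p) {
      v <- d[[p]]
      data.frame(image = d$image[1], property = p,
                 median = stats::median(v), mode = .fd_mode(v),
                 mean = mean(v), variance = stats::var(v),
                 std = stats::sd(v), min = min(v), max = max(v),
                 n = length(v))
    })
    do.call(rbind, rows)
  }))
  rownames(summ) <- NULL
  list(combined = combined, summary = summ)
}
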