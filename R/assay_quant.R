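# Quantification of the downstream validation assays: T2 binding
# fluorescence index (FI), brefeldin-A decay DC50, and pMHC-multimer
# frequencies with cross-reactivity.

# Average replicate MFI measurements (matrix points x replicates) to a mean
# vector; SEM reported alongside. Vectors pass through with SEM = NA.
.collapse_replicates <- function(mfi) {
  if (is.matrix(mfi)) {
    list(mean = rowMeans(mfi),
         sem = apply(mfi, 1, sd) / sqrt(ncol(mfi)))
  } else {
    list(mean = as.numeric(mfi), sem = rep(NA_real_, length(mfi)))
  }
}

#' Construct a T2 binding dose series
#'
#' @param peptide Peptide name.
#' @param concentration_uM Strictly increasing peptide concentrations
#'   (default 5, 10, 20, 50, 100 uM).
#' @param mfi Positive MFI per concentration; a matrix (points x replicates)
#'   is averaged, with SEM retained.
#' @param mfi_background Positive no-peptide control MFI (scalar or
#'   replicate vector, averaged).
#' @return A `binding_series` object.
#' @export
binding_series <- function(peptide, concentration_uM = c(5, 10, 20, 50, 100),
                           mfi, mfi_background) {
  if (any(diff(concentration_uM) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  m <- .collapse_replicates(mfi)
  bg <- mean(mfi_background)
  if (length(m$mean) != length(concentration_uM)) {
    stop("one MFI (set) per concentration required", call. = FALSE)
  }
  if (any(m$mean <= 0) || bg <= 0) {
    stop("MFI values must be positive", call. = FALSE)
  }
  structure(list(peptide = peptide, concentration_uM = concentration_uM,
                 mfi = m$mean, mfi_sem = m$sem, mfi_background = bg),
            class = "binding_series")
}

#' Fluorescence index
#'
#' `FI = (MFI_sample - MFI_background) / MFI_background`. FI is invariant
#' to a common positive rescaling of sample and background. The binder
#' threshold is FI > 0.5 (strict).
#'
#' @param mfi_sample Sample MFI (vectorized).
#' @param mfi_background Positive background (no-peptide) MFI.
#' @return Numeric FI values.
#' @export
fluorescence_index <- function(mfi_sample, mfi_background) {
  if (any(mfi_background <= 0)) {
    stop("domain error: background MFI must be positive", call. = FALSE)
  }
  (mfi_sample - mfi_background) / mfi_background
}

#' Binding profile of a dose series
#'
#' @param series A [binding_series()].
#' @param fi_threshold Binder threshold on FI (strict `>`, default 0.5).
#' @return A `binding_profile` object: per-concentration `fi`, overall
#'   `binder` call (FI above threshold at any concentration), and
#'   `monotone` flag (FI non-decreasing in dose).
#' @export
binding_profile <- function(series, fi_threshold = 0.5) {
  if (length(series$concentration_uM) < 2) {
    stop("binding profile needs >= 2 concentrations", call. = FALSE)
  }
  fi <- fluorescence_index(series$mfi, series$mfi_background)
  structure(list(
    peptide = series$peptide,
    concentration_uM = series$concentration_uM,
    fi = fi,
    binder = any(fi > fi_threshold),
    monotone = all(diff(fi) >= -1e-9)
  ), class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("T2 binding profile [%s]: %s, %s\n", x$peptide,
              if (x$binder) "binder" else "non-binder",
              if (x$monotone) "dose-monotone" else "non-monotone"))
  cat("  FI:", paste(sprintf("%.2f@%guM", x$fi, x$concentration_uM),
                     collapse = "  "), "\n")
  invisible(x)
}

#' Construct a BFA decay time series
#'
#' @param peptide Peptide name.
#' @param timepoints_h Harvest times in hours, starting at 0, strictly
#'   increasing (default 0, 2, 4, 6, 8).
#' @param mfi MFI per timepoint (matrix of replicates averaged); MFI at
#'   time 0 must be positive.
#' @return A `decay_series` object.
#' @export
decay_series <- function(peptide, timepoints_h = c(0, 2, 4, 6, 8), mfi) {
  if (timepoints_h[1] != 0 || any(diff(timepoints_h) <= 0)) {
    stop("timepoints must start at 0 and increase strictly", call. = FALSE)
  }
  m <- .collapse_replicates(mfi)
  if (length(m$mean) != length(timepoints_h)) {
    stop("one MFI (set) per timepoint required", call. = FALSE)
  }
  if (m$mean[1] <= 0) stop("MFI at time 0 must be positive", call. = FALSE)
  structure(list(peptide = peptide, timepoints_h = timepoints_h,
                 mfi = m$mean, mfi_sem = m$sem),
            class = "decay_series")
}

#' Percent of initial MFI remaining over time
#'
#' `MFI(t) / MFI(0) * 100`; by construction 100 at t = 0.
#'
#' @param series A [decay_series()].
#' @return Numeric vector of percentages, one per timepoint.
#' @export
percent_remaining <- function(series) {
  100 * series$mfi / series$mfi[1]
}

#' DC50: time to 50% loss of the initial surface signal
#'
#' In `discrete` mode (the default, matching how sampled-timepoint readouts
#' are reported) DC50 is the first sampled timepoint at which the remaining
#' signal is <= 50%. In `interpolated` mode it is the linear crossing time
#' between the bracketing samples. When no sample reaches 50% the result is
#' "not reached" beyond the last timepoint.
#'
#' @param series A [decay_series()] with >= 2 timepoints.
#' @param mode `"discrete"` or `"interpolated"`.
#' @return A `dc50` object: `hours` (NA when not reached), `reached`,
#'   `mode`, `max_time_h`.
#' @export
dc50 <- function(series, mode = c("discrete", "interpolated")) {
  mode <- match.arg(mode)
  if (length(series$timepoints_h) < 2) {
    stop("DC50 needs >= 2 timepoints", call. = FALSE)
  }
  pct <- percent_remaining(series)
  t <- series$timepoints_h
  below <- which(pct <= 50)
  if (length(below) == 0) {
    res <- list(hours = NA_real_, reached = FALSE, mode = mode,
                max_time_h = max(t))
  } else if (mode == "discrete") {
    res <- list(hours = t[below[1]], reached = TRUE, mode = mode,
                max_time_h = max(t))
  } else {
    i <- below[1]
    hours <- if (i == 1) 0 else {
      t[i - 1] + (pct[i - 1] - 50) / (pct[i - 1] - pct[i]) * (t[i] - t[i - 1])
    }
    res <- list(hours = hours, reached = TRUE, mode = mode,
                max_time_h = max(t))
  }
  structure(res, class = "dc50")
}

#' @export
print.dc50 <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("DC50 (%s): %.2f h\n", x$mode, x$hours))
  } else {
    cat(sprintf("DC50 (%s): not reached (> %g h)\n", x$mode, x$max_time_h))
  }
  invisible(x)
}

#' Multimer-positive frequencies among gated CD3+CD8+ events
#'
#' Gates events on live / CD3-positive / CD8-positive using explicit
#' per-channel thresholds (no automated gating), then reports the
#' percentage of gated events above threshold in each multimer channel, and
#' optionally the cross-reactive percentage per configured TAA--viral pair,
#' operationalized as double positivity in both channels within the same
#' event.
#'
#' @param events Data frame with one row per event: columns `live`
#'   (logical/0-1), `cd3`, `cd8`, plus one intensity column per multimer
#'   channel.
#' @param thresholds Named numeric vector/list: thresholds for `cd3`, `cd8`
#'   and each multimer channel to report.
#' @param pairs Optional named list of length-2 character vectors naming the
#'   (TAA channel, viral channel) of each pair.
#' @return A `multimer_freq` object: `per_channel` (data frame `channel`,
#'   `n_pos`, `percent`), `per_pair` (data frame `pair`, `n_pos`,
#'   `percent`), `n_gated`.
#' @export
multimer_frequencies <- function(events, thresholds, pairs = NULL) {
  thresholds <- unlist(thresholds)
  for (need in c("cd3", "cd8")) {
    if (!need %in% names(thresholds)) {
      stop("configuration error: no threshold for '", need, "'",
           call. = FALSE)
    }
  }
  channels <- setdiff(names(thresholds), c("cd3", "cd8"))
  missing_ch <- setdiff(channels, names(events))
  if (length(missing_ch) > 0) {
    stop("configuration error: channel '", missing_ch[1],
         "' not in event table", call. = FALSE)
  }
  gate <- as.logical(events$live) &
    events$cd3 > thresholds[["cd3"]] & events$cd8 > thresholds[["cd8"]]
  n_gated <- sum(gate)
  if (n_gated == 0) {
    stop("no event passes the live/CD3/CD8 gate", call. = FALSE)
  }
  gated <- events[gate, , drop = FALSE]
  pos <- vapply(channels, function(ch) gated[[ch]] > thresholds[[ch]],
                logical(nrow(gated)))
  if (nrow(gated) == 1L) pos <- matrix(pos, nrow = 1L,
                                       dimnames = list(NULL, channels))
  per_channel <- data.frame(
    channel = channels,
    n_pos = as.integer(colSums(pos)),
    percent = 100 * colSums(pos) / n_gated,
    stringsAsFactors = FALSE, row.names = NULL)
  per_pair <- NULL
  if (!is.null(pairs)) {
    bad <- vapply(pairs, function(p) !all(p %in% channels), TRUE)
    if (any(bad)) {
      stop("configuration error: pair '", names(pairs)[bad][1],
           "' references unknown channel", call. = FALSE)
    }
    n_pos <- vapply(pairs, function(p)
      sum(pos[, p[1]] & pos[, p[2]]), integer(1))
    per_pair <- data.frame(pair = names(pairs), n_pos = as.integer(n_pos),
                           percent = 100 * n_pos / n_gated,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(per_channel = per_channel, per_pair = per_pair,
                 n_gated = n_gated), class = "multimer_freq")
}

#' @export
print.multimer_freq <- function(x, ...) {
  cat("Multimer frequencies (% of", x$n_gated, "gated CD3+CD8+ events)\n")
  for (i in seq_len(nrow(x$per_channel))) {
    cat(sprintf("  %-16s %6.3f%%\n", x$per_channel$channel[i],
                x$per_channel$percent[i]))
  }
  if (!is.null(x$per_pair)) {
    for (i in seq_len(nrow(x$per_pair))) {
      cat(sprintf("  cross %-10s %6.3f%%\n", x$per_pair$pair[i],
                  x$per_pair$percent[i]))
    }
  }
  invisible(x)
}

#' Group-level summary of per-donor multimer frequencies
#'
#' Arithmetic mean of the per-donor percentages within each group, per
#' channel and per cross-reactive pair.
#'
#' @param results List of `multimer_freq` objects, one per donor.
#' @param groups Character vector of group labels (e.g. `"HCC"`,
#'   `"healthy"`), one per donor.
#' @return A list with `per_channel` and `per_pair` data frames
#'   (`group`, `channel`/`pair`, `mean_percent`, `n_donors`).
#' @export
group_summary <- function(results, groups) {
  if (length(results) != length(groups) || length(results) == 0) {
    stop("one group label per donor result required", call. = FALSE)
  }
  summarize <- function(slot, key) {
    tabs <- Map(function(res, grp) {
      tab <- res[[slot]]
      if (is.null(tab)) return(NULL)
      data.frame(group = grp, key = tab[[key]], percent = tab$percent,
                 stringsAsFactors = FALSE)
    }, results, groups)
    all <- do.call(rbind, tabs)
    if (is.null(all)) return(NULL)
    agg <- aggregate(percent ~ group + key, data = all, FUN = mean)
    n <- aggregate(percent ~ group + key, data = all, FUN = length)
    out <- data.frame(group = agg$group, agg$key,
                      mean_percent = agg$percent, n_donors = n$percent,
                      stringsAsFactors = FALSE)
    names(out)[2] <- key
    out[order(out$group, out[[key]]), , drop = FALSE]
  }
  list(per_channel = summarize("per_channel", "channel"),
       per_pair = summarize("per_pair", "pair"))
}
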