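# Population-distribution summaries and the six M-pattern conversions.
#
# A sample's cells at one time point are pooled over all wells and fields
# into one distribution per morphological feature, characterised by the
# mean (AVE), the 10/25/50/75/90% quantile points (linear-interpolation
# estimator), the median (MED = Q50), the interquartile range
# (INT = Q75 - Q25), quartile (Bowley) skewness
# SKEW = (Q75 + Q25 - 2 Q50) / INT and the robust kurtosis
# KURT = (Q90 - Q10) / INT. "Linked" patterns additionally convert each
# quantile into its changing ratio between time points.

SUMMARY_STATS <- c("AVE", "Q10", "Q25", "Q50", "Q75", "Q90", "MED", "INT",
                   "SKEW", "KURT")

#' Summarise one pooled cell-population distribution
#'
#' @param values Numeric vector of per-cell values for one morphological
#'   feature (all objects of one sample at one time point, pooled over
#'   wells and fields). At least 2 values.
#' @return Named numeric vector with elements
#'   `AVE, Q10, Q25, Q50, Q75, Q90, MED, INT, SKEW, KURT`.
#'   If the interquartile range is zero, SKEW and KURT are set to 0 with a
#'   warning.
#' @export
summarize_distribution <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 values to summarise a distribution, got ",
         length(values))
  if (any(!is.finite(values))) stop("values must be finite")
  q <- quantile(values, QUANTILE_POINTS, names = FALSE, type = 7)
  int <- q[4] - q[2]
  if (int == 0) {
    warning("zero interquartile range: SKEW and KURT set to 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- (q[4] + q[2] - 2 * q[3]) / int
    kurt <- (q[5] - q[1]) / int
  }
  c(AVE = mean(values), Q10 = q[1], Q25 = q[2], Q50 = q[3], Q75 = q[4],
    Q90 = q[5], MED = q[3], INT = int, SKEW = skew, KURT = kurt)
}

#' Ratio of a statistic between two time points
#'
#' @param earlier Value at the earlier time point (denominator).
#' @param later Value at the later time point (numerator).
#' @param sentinel Value returned (with a warning) where `earlier` is 0;
#'   the default 0 keeps degenerate ratios from injecting infinities into
#'   model fitting.
#' @return `later / earlier`, elementwise.
#' @export
linked_ratio <- function(earlier, later, sentinel = 0) {
  stopifnot(length(earlier) == length(later),
            all(is.finite(earlier)), all(is.finite(later)))
  out <- later / earlier
  zero <- earlier == 0
  if (any(zero)) {
    warning(sum(zero), " ratio(s) with zero denominator set to sentinel ",
            sentinel)
    out[zero] <- sentinel
  }
  out
}

#' Canonical feature labels of one M-pattern
#'
#' The label order is fixed (feature-major, then statistic, then time
#' point; object counts appended last) and is the order
#' [build_mpattern()] emits values in.
#'
#' @param pattern_id Integer 1-6.
#' @param hours Acquisition hours (default 24, 48, 72, 96).
#' @return Character vector of feature labels.
#' @export
mpattern_names <- function(pattern_id, hours = c(24, 48, 72, 96)) {
  stopifnot(pattern_id %in% 1:6)
  qs <- names(QUANTILE_POINTS)
  h <- hours
  iv <- function(h2, h1) sprintf("h%dover%d", h2, h1)
  consec <- cbind(h[-length(h)], h[-1])
  switch(as.character(pattern_id),
    "1" = c(as.vector(t(outer(MORPH_FEATURES, h,
                              function(f, hh) sprintf("%s_AVE_h%d", f, hh)))),
            sprintf("object_count_h%d", h)),
    "2" = c(unlist(lapply(MORPH_FEATURES, function(f)
              unlist(lapply(qs, function(q)
                sprintf("%s_%s_h%d", f, q, h))))),
            sprintf("object_count_h%d", h)),
    "3" = c(unlist(lapply(MORPH_FEATURES, function(f)
              unlist(lapply(qs, function(q)
                sprintf("%s_%s_%s", f, q,
                        iv(consec[, 2], consec[, 1])))))),
            sprintf("object_count_%s", iv(consec[, 2], consec[, 1]))),
    "4" = c(unlist(lapply(MORPH_FEATURES, function(f)
              unlist(lapply(c("MED", "INT", "SKEW", "KURT"), function(s)
                sprintf("%s_%s_h%d", f, s, h))))),
            sprintf("object_count_h%d", h)),
    "5" = c(unlist(lapply(MORPH_FEATURES, function(f)
              sprintf("%s_%s_%s", f, qs, iv(h[length(h)], h[1])))),
            sprintf("object_count_%s", iv(h[length(h)], h[1]))),
    "6" = c(unlist(lapply(MORPH_FEATURES, function(f)
              sprintf("%s_%s_h%d", f, qs, h[1]))),
            sprintf("object_count_h%d", h[1]))
  )
}

hours_required <- function(pattern_id, hours) {
  switch(as.character(pattern_id),
         "5" = hours[c(1, length(hours))],
         "6" = hours[1],
         hours)
}

#' Build one M-pattern feature vector for a sample
#'
#' Converts per-time-point distribution summaries into one of the six
#' fixed-length per-sample feature vectors:
#' \describe{
#'   \item{1 (40)}{AVE of the nine features at all four time points, plus
#'     object count at each time point.}
#'   \item{2 (184)}{Five quantile points of the nine features at all four
#'     time points, plus counts.}
#'   \item{3 (138)}{Ratios of the five quantiles over the three
#'     consecutive intervals, plus three count ratios.}
#'   \item{4 (148)}{MED, INT, SKEW, KURT of the nine features at all four
#'     time points, plus counts.}
#'   \item{5 (46)}{Ratios of the five quantiles over the single first-day
#'     to last-day interval, plus one count ratio.}
#'   \item{6 (46)}{Five quantiles at the first time point only, plus its
#'     count.}
#' }
#'
#' @param pattern_id Integer 1-6.
#' @param summaries Named list, one element per acquisition hour (names are
#'   the hours as character). Each element is a list with `stats` (data
#'   frame, rows = the nine morphological features, columns the
#'   [summarize_distribution()] statistics) and `count` (mean object count
#'   per image).
#' @param hours Acquisition hours; patterns 5 and 6 only require the
#'   subsets they use.
#' @param sample_id Optional sample identifier carried in the result.
#' @return An `mpattern_vector`: list with `pattern_id`, `sample_id`,
#'   `names` and `values` (named numeric vector).
#' @export
build_mpattern <- function(pattern_id, summaries, hours = c(24, 48, 72, 96),
                           sample_id = NA) {
  stopifnot(pattern_id %in% 1:6)
  need <- hours_required(pattern_id, hours)
  missing_h <- setdiff(as.character(need), names(summaries))
  if (length(missing_h))
    stop("missing summaries for hour(s): ", paste(missing_h, collapse = ", "))
  get_stat <- function(h, f, s) summaries[[as.character(h)]]$stats[f, s]
  get_count <- function(h) summaries[[as.character(h)]]$count
  qs <- names(QUANTILE_POINTS)
  consec <- cbind(hours[-length(hours)], hours[-1])

  vals <- switch(as.character(pattern_id),
    "1" = c(unlist(lapply(MORPH_FEATURES, function(f)
              vapply(hours, function(h) get_stat(h, f, "AVE"), numeric(1)))),
            vapply(hours, get_count, numeric(1))),
    "2" = c(unlist(lapply(MORPH_FEATURES, function(f)
              unlist(lapply(qs, function(q)
                vapply(hours, function(h) get_stat(h, f, q), numeric(1)))))),
            vapply(hours, get_count, numeric(1))),
    "3" = c(unlist(lapply(MORPH_FEATURES, function(f)
              unlist(lapply(qs, function(q)
                vapply(seq_len(nrow(consec)), function(i)
                  linked_ratio(get_stat(consec[i, 1], f, q),
                               get_stat(consec[i, 2], f, q)),
                  numeric(1)))))),
            vapply(seq_len(nrow(consec)), function(i)
              linked_ratio(get_count(consec[i, 1]), get_count(consec[i, 2])),
              numeric(1))),
    "4" = c(unlist(lapply(MORPH_FEATURES, function(f)
              unlist(lapply(c("MED", "INT", "SKEW", "KURT"), function(s)
                vapply(hours, function(h) get_stat(h, f, s), numeric(1)))))),
            vapply(hours, get_count, numeric(1))),
    "5" = c(unlist(lapply(MORPH_FEATURES, function(f)
              vapply(qs, function(q)
                linked_ratio(get_stat(hours[1], f, q),
                             get_stat(hours[length(hours)], f, q)),
                numeric(1)))),
            linked_ratio(get_count(hours[1]), get_count(hours[length(hours)]))),
    "6" = c(unlist(lapply(MORPH_FEATURES, function(f)
              vapply(qs, function(q) get_stat(hours[1], f, q), numeric(1)))),
            get_count(hours[1]))
  )
  nm <- mpattern_names(pattern_id, hours)
  stopifnot(length(vals) == length(nm))
  structure(list(pattern_id = pattern_id, sample_id = sample_id,
                 names = nm, values = setNames(as.numeric(vals), nm)),
            class = "mpattern_vector")
}

#' Summarise measured images into per-sample, per-hour distributions
#'
#' Pools the per-object measurements of all images of one sample at each
#' time point into the `summaries` structure [build_mpattern()] consumes.
#'
#' @param morphologies List of `image_morphology` results (all images of
#'   one sample across wells, fields and hours).
#' @return Named list by hour with `stats` and `count` (mean retained
#'   object count per image at that hour).
#' @export
summarize_sample <- function(morphologies) {
  hours <- sort(unique(vapply(morphologies, function(m) as.integer(m$hour),
                              integer(1))))
  out <- lapply(hours, function(h) {
    ms <- Filter(function(m) m$hour == h, morphologies)
    pooled <- do.call(rbind, lapply(ms, function(m) m$objects))
    stats <- do.call(rbind, lapply(MORPH_FEATURES, function(f)
      summarize_distribution(pooled[[f]])))
    rownames(stats) <- MORPH_FEATURES
    list(stats = as.data.frame(stats),
         count = mean(vapply(ms, function(m) m$object_count, numeric(1))))
  })
  names(out) <- as.character(hours)
  out
}

#' Assemble a training table for one potential and one input configuration
#'
#' @param features Named list of sample-by-feature matrices `mp1` ... `mp6`
#'   (as produced by [simulate_feature_bundle()] or from measured images).
#' @param potentials Data frame with `sample_id` and one column per
#'   potential type (`osteo`, `adipo`, `chondro`, `pdt`).
#' @param potential_type Which potential to use as the response.
#' @param inputs One of `"genes"`, `"genes+mp1"`, `"mp1"` ... `"mp6"`.
#' @param genes Optional genes x samples matrix (required for gene
#'   configurations).
#' @return List with `X` (samples x features matrix), `y` (named numeric
#'   response), `sample_ids`, `potential_type`, `inputs`, and `provenance`
#'   (data frame describing each column).
#' @export
assemble_dataset <- function(features, potentials, potential_type, inputs,
                             genes = NULL) {
  stopifnot(potential_type %in% POTENTIAL_TYPES)
  valid <- c("genes", "genes+mp1", paste0("mp", 1:6))
  if (length(inputs) != 1 || !inputs %in% valid)
    stop("inputs must be one of: ", paste(valid, collapse = ", "))
  blocks <- list()
  if (inputs %in% c("genes", "genes+mp1")) {
    if (is.null(genes)) stop("gene table required for inputs = ", inputs)
    blocks$genes <- t(genes)
  }
  if (grepl("mp", inputs)) {
    k <- sub(".*mp", "mp", inputs)
    if (is.null(features[[k]])) stop("feature matrix ", k, " not supplied")
    blocks[[k]] <- features[[k]]
  }
  ids <- potentials$sample_id
  for (nm in names(blocks)) {
    miss <- setdiff(ids, rownames(blocks[[nm]]))
    extra <- setdiff(rownames(blocks[[nm]]), ids)
    if (length(miss) || length(extra))
      stop("sample mismatch in block '", nm, "': missing [",
           paste(miss, collapse = ", "), "] extra [",
           paste(extra, collapse = ", "), "]")
    blocks[[nm]] <- blocks[[nm]][ids, , drop = FALSE]
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- ids
  y <- setNames(potentials[[potential_type]], ids)
  prov <- parse_feature_provenance(colnames(X))
  list(X = X, y = y, sample_ids = ids, potential_type = potential_type,
       inputs = inputs, provenance = prov)
}

# Decompose feature labels into (source, feature, statistic, hours).
parse_feature_provenance <- function(nm) {
  feat_rx <- paste(MORPH_FEATURES, collapse = "|")
  out <- data.frame(name = nm, source = rep("gene", length(nm)),
                    feature = nm, statistic = rep(NA_character_, length(nm)),
                    hours = rep(NA_character_, length(nm)),
                    stringsAsFactors = FALSE)
  m <- regexec(sprintf("^(%s|object_count)(_(AVE|Q10|Q25|Q50|Q75|Q90|MED|INT|SKEW|KURT))?_(h[0-9]+(over[0-9]+)?)$",
                       feat_rx), nm)
  for (i in seq_along(nm)) {
    g <- regmatches(nm[i], m[i])[[1]]
    if (length(g)) {
      out$source[i] <- if (g[2] == "object_count") "count" else "morphology"
      out$feature[i] <- g[2]
      out$statistic[i] <- if (nzchar(g[4])) g[4] else
        if (g[2] == "object_count") "count" else NA_character_
      out$hours[i] <- g[5]
    }
  }
  out
}
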