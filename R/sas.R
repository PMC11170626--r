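# Structure-activity-similarity (SAS) maps. Each compound pair is a
# point (structural similarity, activity-profile similarity); the plane
# is split into four regions by a per-fingerprint structural threshold
# (mean + 2 sample SD of the pairwise distribution) and a fixed activity
# threshold of 0.1. Region II holds structurally similar pairs with
# similar activity profiles (smooth SAR); region IV holds structurally
# similar pairs with discordant profiles - pseudo-activity cliffs,
# "pseudo" because an unreported activity may simply be untested.

#' SAS thresholds from a pairwise similarity table
#'
#' The structural threshold is mean + 2 standard deviations (sample,
#' n - 1) of each fingerprint's pairwise similarity distribution over
#' the without-self pairs; values exceeding 1 are capped at 1 with a
#' warning. The activity threshold is fixed (default 0.1).
#'
#' @param pairs a [pairwise_similarity()] table, or for a single
#'   fingerprint a numeric vector of similarities.
#' @param kinds fingerprint columns to use (default: those present).
#' @param activity_threshold activity-similarity cut, in (0, 1).
#' @return object of class \code{sas_thresholds}: list with
#'   \code{structural} (named numeric), \code{activity},
#'   \code{mean}, \code{sd} (named, per fingerprint).
#' @export
sas_thresholds <- function(pairs, kinds = NULL, activity_threshold = 0.1) {
  stopifnot(activity_threshold > 0, activity_threshold < 1)
  if (is.numeric(pairs) && is.null(dim(pairs))) {
    pairs <- data.frame(similarity = pairs)
    kinds <- "similarity"
  }
  if (is.null(kinds)) kinds <- intersect(fingerprint_kinds(), names(pairs))
  if (!length(kinds)) stop("no fingerprint similarity columns found")
  mu <- sdv <- thr <- stats::setNames(numeric(length(kinds)), kinds)
  for (k in kinds) {
    v <- pairs[[k]]
    if (length(v) < 2) stop("need >= 2 pairwise values for '", k, "'")
    mu[k] <- mean(v)
    sdv[k] <- stats::sd(v)          # sample SD (n - 1)
    if (sdv[k] == 0) {
      stop("degenerate similarity distribution for '", k,
           "': zero variance")
    }
    thr[k] <- mu[k] + 2 * sdv[k]
    if (thr[k] > 1) {
      warning("structural threshold for '", k, "' (", round(thr[k], 4),
              ") exceeds 1; capped at 1", call. = FALSE)
      thr[k] <- 1
    }
  }
  structure(list(structural = thr, activity = activity_threshold,
                 mean = mu, sd = sdv),
            class = "sas_thresholds")
}

#' Classify compound pairs into SAS regions
#'
#' Per fingerprint: region II = structural similarity strictly greater
#' than the structural threshold and activity similarity strictly
#' greater than the activity threshold; region IV = structurally above
#' threshold, activity at or below threshold; regions I and III are the
#' low-structural-similarity counterparts. The four regions partition
#' all pairs.
#'
#' @param pairs a [pairwise_similarity()] table.
#' @param thresholds a [sas_thresholds()] object.
#' @return the table with one added \code{region_<kind>} factor column
#'   (levels I-IV) per fingerprint, class \code{sas_classification};
#'   attribute \code{thresholds} records the cuts used.
#' @export
classify_sas <- function(pairs, thresholds) {
  stopifnot(inherits(thresholds, "sas_thresholds"))
  kinds <- names(thresholds$structural)
  missing <- setdiff(kinds, names(pairs))
  if (length(missing)) stop("missing similarity columns: ",
                            paste(missing, collapse = ", "))
  if (!"activity_similarity" %in% names(pairs)) {
    stop("pairs table lacks activity_similarity")
  }
  if (anyNA(pairs[, c(kinds, "activity_similarity")])) {
    stop("similarities contain missing values")
  }
  act_hi <- pairs$activity_similarity > thresholds$activity
  for (k in kinds) {
    str_hi <- pairs[[k]] > thresholds$structural[[k]]
    region <- ifelse(str_hi,
                     ifelse(act_hi, "II", "IV"),
                     ifelse(act_hi, "I", "III"))
    pairs[[paste0("region_", k)]] <- factor(region, levels = c("I", "II", "III", "IV"))
  }
  structure(pairs, thresholds = thresholds,
            class = c("sas_classification", "data.frame"))
}

#' Region counts per fingerprint
#'
#' @param classification a [classify_sas()] result.
#' @return matrix: fingerprints x regions I-IV.
#' @export
sas_region_counts <- function(classification) {
  stopifnot(inherits(classification, "sas_classification"))
  cols <- grep("^region_", names(classification), value = TRUE)
  t(vapply(cols, function(cl) table(classification[[cl]]),
           integer(4))) |>
    `rownames<-`(sub("^region_", "", cols))
}

#' Consensus pairs across all fingerprints
#'
#' Pairs assigned the requested region under every classified
#' fingerprint, sorted by mean structural similarity descending. The
#' consensus requirement filters hash- or dictionary-specific artifacts
#' of any single fingerprint. Pairs in which either compound has an
#' all-zero specific profile are retained but flagged
#' (\code{activity_undefined}); for region IV these are the annex of
#' pseudo-cliffs driven by possibly untested compounds.
#'
#' @param classification a [classify_sas()] result.
#' @param region \code{"II"} (similar structure, similar profile) or
#'   \code{"IV"} (pseudo-activity cliffs).
#' @return data.frame of consensus pairs with names, per-fingerprint
#'   similarities, \code{mean_structural_similarity},
#'   \code{activity_similarity} and flags.
#' @export
consensus_pairs <- function(classification, region = c("II", "IV")) {
  stopifnot(inherits(classification, "sas_classification"))
  region <- match.arg(region)
  cols <- grep("^region_", names(classification), value = TRUE)
  kinds <- sub("^region_", "", cols)
  hit <- Reduce(`&`, lapply(cols, function(cl) classification[[cl]] == region))
  out <- as.data.frame(classification)[hit, , drop = FALSE]
  out$mean_structural_similarity <- rowMeans(out[, kinds, drop = FALSE])
  out <- out[order(-out$mean_structural_similarity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plottable SAS point set for one fingerprint
#'
#' @param classification a [classify_sas()] result.
#' @param kind fingerprint kind.
#' @return data.frame \code{id_i}, \code{id_j}, \code{structural},
#'   \code{activity}, \code{region}.
#' @export
sas_points <- function(classification, kind = fingerprint_kinds()) {
  stopifnot(inherits(classification, "sas_classification"))
  kind <- match.arg(kind)
  rc <- paste0("region_", kind)
  if (!rc %in% names(classification)) stop("kind '", kind, "' not classified")
  data.frame(id_i = classification$id_i, id_j = classification$id_j,
             structural = classification[[kind]],
             activity = classification$activity_similarity,
             region = classification[[rc]],
             stringsAsFactors = FALSE)
}

#' Write an interactive HTML SAS map
#'
#' Self-contained scatter plot (inline SVG with hover tooltips naming
#' the compound pair); mirrors the shareable HTML maps that usually
#' accompany this analysis.
#'
#' @param points a [sas_points()] data.frame; optionally with
#'   \code{name_i}/\code{name_j} columns for tooltips.
#' @param path output .html path.
#' @param title plot title.
#' @return \code{path}, invisibly.
#' @export
write_sas_html <- function(points, path, title = "SAS map") {
  w <- 640; h <- 640; pad <- 50
  px <- pad + points$structural * (w - 2 * pad)
  py <- h - pad - points$activity * (h - 2 * pad)
  col <- c(I = "#888888", II = "#e7298a", III = "#bbbbbb", IV = "#1b9e77")[
    as.character(points$region)]
  tip <- if (all(c("name_i", "name_j") %in% names(points))) {
    paste0(points$name_i, " vs ", points$name_j)
  } else paste0(points$id_i, " vs ", points$id_j)
  circles <- sprintf(
    "<circle cx='%.1f' cy='%.1f' r='3' fill='%s' fill-opacity='0.6'><title>%s (%.3f, %.3f)</title></circle>",
    px, py, col, .html_escape(tip), points$structural, points$activity)
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    paste0("<title>", .html_escape(title), "</title></head><body>"),
    paste0("<h1>", .html_escape(title), "</h1>"),
    sprintf("<svg width='%d' height='%d' style='border:1px solid #ccc'>", w, h),
    sprintf("<text x='%d' y='%d'>structural similarity</text>", w %/% 2 - 60, h - 10),
    sprintf("<text x='15' y='%d' transform='rotate(-90 15 %d)'>activity similarity</text>",
            h %/% 2, h %/% 2),
    circles,
    "</svg></body></html>"), path)
  invisible(path)
}
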