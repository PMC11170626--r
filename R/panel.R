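#' Target panels
#'
#' A target panel is the ordered set of epigenetic targets against which a
#' library's binary activity profiles are recorded, each classified by its
#' mechanistic role: writers add chemical marks to histones or DNA (DNMTs,
#' HATs, EZH2, PRMT1), erasers remove them (HDACs, sirtuins, lysine
#' demethylases), and readers recognize them (bromodomain proteins).
#' Families group targets for compounds whose reported activity has only
#' family-level resolution (e.g. "a DNMT inhibitor", protein unspecified).
#'
#' @param targets character vector of unique target names, in panel order.
#' @param classes character vector, same length, each one of
#'   \code{"writer"}, \code{"eraser"}, \code{"reader"}.
#' @param families named list mapping family name to a character vector of
#'   member targets (members need not exhaust the panel).
#' @return An object of class \code{target_panel}.
#' @seealso [default_target_panel()]
#' @export
target_panel <- function(targets, classes, families = list()) {
  stopifnot(is.character(targets), length(targets) >= 1,
            length(classes) == length(targets))
  if (anyDuplicated(targets)) stop("target names must be unique")
  if (!all(classes %in% c("writer", "eraser", "reader"))) {
    stop("classes must be 'writer', 'eraser' or 'reader'")
  }
  structure(list(targets = targets, classes = classes, families = families),
            class = "target_panel")
}

#' The default 46-target epigenetic panel
#'
#' The panel covers 8 writers, 37 erasers and 1 reader, in that order:
#' DNA methyltransferases, histone acetyltransferases, EZH2 and PRMT1;
#' the HDAC and sirtuin deacetylases and the lysine demethylases; and the
#' BET/BRD4 bromodomain reader. Three family-level flags (DNMT, HDAC, KDM
#' families) accompany the panel for compounds annotated only at family
#' resolution.
#'
#' @return A \code{target_panel} with 46 targets.
#' @export
default_target_panel <- function() {
  writers <- c("DNMT1", "DNMT3a", "DNMT3b", "HAT/Ep300", "HAT2B/Ep300",
               "HAT3B/p300", "EZH2", "PRMT1")
  erasers <- c(paste0("HDAC", 1:11),
               paste0("SIRT", 1:7),
               "LSD1",
               "KDM1A", "KDM1B", "KDM2A", "KDM2B", "KDM3A", "KDM3B",
               "KDM4A", "KDM4B", "KDM4C", "KDM4D",
               "KDM5A", "KDM5B", "KDM5C", "KDM5D",
               "KDM6A", "KDM6B", "KDM7A", "KDM8")
  readers <- "BET/BRD4"
  targets <- c(writers, erasers, readers)
  classes <- c(rep("writer", length(writers)),
               rep("eraser", length(erasers)),
               rep("reader", length(readers)))
  families <- list(
    "DNMT family" = c("DNMT1", "DNMT3a", "DNMT3b"),
    "HDAC family" = c(paste0("HDAC", 1:11), paste0("SIRT", 1:7)),
    "KDM family"  = c("LSD1", grep("^KDM", erasers, value = TRUE))
  )
  target_panel(targets, classes, families)
}

#' @export
print.target_panel <- function(x, ...) {
  tab <- table(factor(x$classes, levels = c("writer", "eraser", "reader")))
  cat(sprintf("target_panel: %d targets (%d writers, %d erasers, %d readers), %d families\n",
              length(x$targets), tab[["writer"]], tab[["eraser"]],
              tab[["reader"]], length(x$families)))
  invisible(x)
}

#' @export
length.target_panel <- function(x) length(x$targets)
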