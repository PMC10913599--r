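#' Remove the global signal from each volume
#'
#' For each volume (row) x_t, subtracts the across-ROI mean and divides by the
#' across-ROI population standard deviation (divisor = number of ROIs, not
#' n - 1). After this step every row has mean 0 and population SD 1, so the
#' global field power sigma_t equals 1 for all t.
#'
#' @param X T x N numeric matrix, rows = volumes.
#' @return A list with `data` (the standardized T x N matrix) and `trace`, a
#'   list with per-volume `mean`, `sd` (the removed global signal and GFP) and
#'   `n_rois_used`.
#' @export
remove_global_signal <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("global signal removal needs at least 2 ROIs")
  mu <- rowMeans(X)
  centered <- X - mu
  sd_t <- sqrt(rowMeans(centered^2))  # population divisor N
  if (any(sd_t == 0)) {
    t_bad <- which(sd_t == 0)[1L]
    stop("degenerate volume t=", t_bad,
         ": signal is constant across ROIs (sigma_t = 0)")
  }
  list(
    data = centered / sd_t,
    trace = list(mean = mu, sd = sd_t, n_rois_used = ncol(X))
  )
}

#' Describe the left/right symmetry structure of an ROI set
#'
#' @param pairs Two-column integer matrix (or list of length-2 vectors) of
#'   (left, right) ROI column indices to be averaged.
#' @param midline Integer vector of midline ROI column indices passed through
#'   unchanged.
#' @param n_rois Total number of ROI columns the map must cover.
#' @return An object of class `symmetry_map`.
#' @export
symmetry_map <- function(pairs, midline = integer(0), n_rois = NULL) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) pairs <- matrix(integer(0), 0L, 2L)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  used <- c(as.vector(pairs), midline)
  if (anyDuplicated(used))
    stop("symmetry map assigns ROI index ", used[duplicated(used)][1L],
         " more than once")
  if (!is.null(n_rois)) {
    if (length(used) != n_rois || !setequal(used, seq_len(n_rois)))
      stop("symmetry map must cover every ROI index 1..", n_rois,
           " exactly once")
  }
  structure(list(pairs = pairs, midline = midline), class = "symmetry_map")
}

#' Read a symmetry map from a two-column CSV
#'
#' Format: header `roi_index,partner_or_MID`; a row `i,j` (with i < j listed
#' once) declares a symmetric pair, and `i,MID` declares a midline ROI.
#'
#' @param path CSV path.
#' @param n_rois Optional total ROI count for coverage validation.
#' @return An object of class `symmetry_map`.
#' @export
read_symmetry_map <- function(path, n_rois = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("roi_index", "partner_or_MID") %in% names(df)))
    stop("symmetry map CSV needs columns roi_index,partner_or_MID")
  is_mid <- toupper(trimws(df$partner_or_MID)) == "MID"
  pairs <- cbind(as.integer(df$roi_index[!is_mid]),
                 as.integer(df$partner_or_MID[!is_mid]))
  symmetry_map(pairs, midline = as.integer(df$roi_index[is_mid]),
               n_rois = n_rois)
}

#' Average symmetrically located ROI pairs
#'
#' Replaces each (left, right) pair of columns by their arithmetic mean and
#' passes midline columns through. Output column order is the pairs in the
#' order given, then the midline ROIs in the order given.
#'
#' @param X T x N matrix.
#' @param map A [symmetry_map()] covering all N columns.
#' @return T x N' matrix with N' = n_pairs + n_midline.
#' @export
aggregate_symmetric <- function(X, map) {
  X <- as.matrix(X)
  stopifnot(inherits(map, "symmetry_map"))
  used <- c(as.vector(map$pairs), map$midline)
  if (length(used) && (max(used) > ncol(X) || min(used) < 1L))
    stop("symmetry map references ROI index out of range 1..", ncol(X))
  if (!setequal(used, seq_len(ncol(X))))
    stop("symmetry map must cover all ", ncol(X), " ROI columns exactly once")
  np <- nrow(map$pairs)
  out <- matrix(0, nrow(X), np + length(map$midline))
  if (np > 0L)
    out[, seq_len(np)] <- (X[, map$pairs[, 1L], drop = FALSE] +
                             X[, map$pairs[, 2L], drop = FALSE]) / 2
  if (length(map$midline))
    out[, np + seq_along(map$midline)] <- X[, map$midline, drop = FALSE]
  out
}

#' Apply one of the composite global-signal treatments
#'
#' The three treatments compared for the default mode network are compositions
#' of global signal removal (GSR) and symmetric-ROI aggregation:
#' \describe{
#'   \item{treatment 1}{GSR over the input ROI set, then symmetric aggregation.}
#'   \item{treatment 2}{treatment 1 followed by a final GSR over the
#'     aggregated ROIs (the default: it gives the best clustering quality, and
#'     guarantees sigma_t = 1 downstream).}
#'   \item{treatment 3}{GSR over the input ROI set only, no aggregation.}
#'   \item{none}{pass-through, for comparison runs without GSR.}
#' }
#' An optional wider first-stage GSR (a global signal defined over a superset
#' of ROIs, e.g. 30 coordinate-system ROIs around a 12-ROI network) is applied
#' when `pre_stage_cols` selects the target columns out of a wider matrix;
#' when `X` already contains only the target ROIs the pre-stage is skipped
#' with a message, because the discarded columns cannot be recovered.
#'
#' @param X T x N (or T x N_wide) matrix.
#' @param treatment One of `"1"`, `"2"`, `"3"`, `"none"` (integers accepted).
#' @param map [symmetry_map()] over the target ROIs; required for treatments
#'   1 and 2.
#' @param pre_stage_cols Optional integer indices of the target ROI columns
#'   within a wider `X`; triggers the first-stage GSR over all of `X`.
#' @return T x N' matrix after the treatment.
#' @export
apply_treatment <- function(X, treatment = c("2", "1", "3", "none"),
                            map = NULL, pre_stage_cols = NULL) {
  treatment <- match.arg(as.character(treatment[[1L]]),
                         c("2", "1", "3", "none"))
  X <- as.matrix(X)
  if (treatment == "none") return(X)
  if (!is.null(pre_stage_cols)) {
    if (length(pre_stage_cols) < ncol(X)) {
      X <- remove_global_signal(X)$data[, pre_stage_cols, drop = FALSE]
    } else {
      X <- remove_global_signal(X)$data
    }
  } else {
    message("no wider ROI set supplied; first-stage global signal removal ",
            "over a superset of ROIs is skipped")
  }
  X <- remove_global_signal(X)$data  # GSR over the target ROIs
  if (treatment == "3") return(X)
  if (is.null(map))
    stop("treatments 1 and 2 require a symmetry map for ROI aggregation")
  X <- aggregate_symmetric(X, map)
  if (treatment == "1") return(X)
  remove_global_signal(X)$data       # treatment 2: final GSR over aggregated
}
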