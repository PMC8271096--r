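# BOLD dataset container: an ordered list of session matrices (time x region)
# sharing one sampling interval, plus their row-wise concatenation.

#' Construct a BOLD dataset from session matrices
#'
#' @param sessions List of numeric matrices, each `T_i x N` (time along
#'   rows, regions along columns); all sessions must share `N` and contain
#'   only finite values.
#' @param tr Sampling interval (repetition time) in seconds.
#' @return A `bold_dataset` with fields `sessions`, `tr`, `concatenated`.
#' @export
#' @examples
#' b <- bold_dataset(list(matrix(rnorm(40), 10, 4)), tr = 0.72)
bold_dataset <- function(sessions, tr) {
  if (!is.list(sessions) || length(sessions) == 0) {
    stop("`sessions` must be a non-empty list of matrices", call. = FALSE)
  }
  ns <- vapply(sessions, ncol, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all sessions must have the same number of regions", call. = FALSE)
  }
  if (!all(vapply(sessions, function(s) all(is.finite(s)), logical(1)))) {
    stop("BOLD sessions must contain only finite values", call. = FALSE)
  }
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  structure(
    list(
      sessions = sessions,
      tr = tr,
      concatenated = do.call(rbind, sessions)
    ),
    class = "bold_dataset"
  )
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf(
    "<bold_dataset: %d sessions x %s volumes, %d regions, TR = %g s>\n",
    length(x$sessions),
    paste(unique(vapply(x$sessions, nrow, integer(1))), collapse = "/"),
    ncol(x$concatenated), x$tr
  ))
  invisible(x)
}

# Pearson FC matrices: one per session plus one for the concatenation.
# Every empirical FC (eFC) is symmetric with unit diagonal.
compute_efc_list <- function(bold) {
  stopifnot(inherits(bold, "bold_dataset"))
  mats <- c(bold$sessions, list(bold$concatenated))
  names(mats) <- c(
    sprintf("session%d", seq_along(bold$sessions)),
    "concatenated"
  )
  lapply(mats, function(m) {
    sds <- apply(m, 2, pop_sd)
    if (any(sds == 0)) {
      stop(
        sprintf(
          "constant BOLD signal in region(s) %s: correlation undefined",
          paste(which(sds == 0), collapse = ", ")
        ),
        call. = FALSE
      )
    }
    fc <- cor(m)
    fc[!is.finite(fc)] <- 0
    diag(fc) <- 1
    (fc + t(fc)) / 2
  })
}
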