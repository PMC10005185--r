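#' Physicochemical library filter criteria
#'
#' Selection thresholds for pre-screening a ligand library.  The shipped
#' defaults are the screen's published constants: molecular weight in
#' [200, 350] Da, at most 2 hydrogen-bond donor atoms, and 1 to 5
#' hydrogen-bond acceptors.  All bounds are inclusive.
#'
#' @param mw_min,mw_max molecular-weight bounds, Da.
#' @param hbd_max maximum donor heavy-atom count.
#' @param hba_min,hba_max acceptor heavy-atom count bounds.
#' @return a `filter_criteria` list.
#' @export
filter_criteria <- function(mw_min = 200, mw_max = 350, hbd_max = 2,
                            hba_min = 1, hba_max = 5) {
  stopifnot(mw_min < mw_max, hba_min <= hba_max,
            mw_min >= 0, hbd_max >= 0, hba_min >= 0)
  structure(list(mw_min = mw_min, mw_max = mw_max, hbd_max = hbd_max,
                 hba_min = hba_min, hba_max = hba_max),
            class = "filter_criteria")
}

#' Test a molecule against filter criteria
#'
#' @param mol an `agmol`.
#' @param criteria a [filter_criteria()] object.
#' @return list with `pass` (logical), `reasons` (character vector of
#'   failing codes among mw_below, mw_above, hbd_above, hba_below,
#'   hba_above; empty when passing) and the measured `mw`, `hbd`, `hba`.
#' @examples
#' water <- molecule(data.frame(element = "O", name = "O1", x = 0, y = 0, z = 0))
#' passes_filter(water, filter_criteria())$reasons  # "mw_below"
#' @export
passes_filter <- function(mol, criteria = filter_criteria()) {
  typing <- type_atoms(mol)
  mw <- molecular_weight(mol)
  hbd <- count_hbd(mol, typing)
  hba <- count_hba(mol, typing)
  reasons <- character()
  if (mw < criteria$mw_min) reasons <- c(reasons, "mw_below")
  if (mw > criteria$mw_max) reasons <- c(reasons, "mw_above")
  if (hbd > criteria$hbd_max) reasons <- c(reasons, "hbd_above")
  if (hba < criteria$hba_min) reasons <- c(reasons, "hba_below")
  if (hba > criteria$hba_max) reasons <- c(reasons, "hba_above")
  list(pass = length(reasons) == 0L, reasons = reasons,
       mw = mw, hbd = hbd, hba = hba)
}

#' Filter an SDF library by physicochemical criteria
#'
#' Reads a multi-molecule SDF, writes the passing molecules unchanged to
#' `sdf_out` and a per-molecule report to `report_out`.  A molecule that
#' cannot be parsed or typed is counted as failed with reason
#' `parse_error`; the run continues.
#'
#' @param sdf_in input SDF path.
#' @param criteria a [filter_criteria()] object.
#' @param sdf_out path for passing molecules (optional, `NULL` to skip).
#' @param report_out path for the per-molecule TSV report (optional).
#' @return list of counts: `read`, `passed`, `failed` and
#'   `failed_by_reason` (named integer vector).  Counts conserve:
#'   read = passed + failed.
#' @export
filter_library <- function(sdf_in, criteria = filter_criteria(),
                           sdf_out = NULL, report_out = NULL) {
  poses <- tryCatch(read_sdf(sdf_in), error = function(e) list())
  kept <- list()
  rows <- list()
  reasons_all <- character()
  n_parse_err <- 0L
  for (k in seq_along(poses)) {
    res <- tryCatch(passes_filter(poses[[k]]$molecule, criteria),
                    error = function(e) NULL)
    if (is.null(res)) {
      n_parse_err <- n_parse_err + 1L
      reasons_all <- c(reasons_all, "parse_error")
      rows[[k]] <- data.frame(title = poses[[k]]$molecule$title,
                              mw = NA_real_, hbd = NA_integer_,
                              hba = NA_integer_, pass = FALSE,
                              reasons = "parse_error")
      next
    }
    if (res$pass) kept[[length(kept) + 1L]] <- poses[[k]]
    reasons_all <- c(reasons_all, res$reasons)
    rows[[k]] <- data.frame(title = poses[[k]]$molecule$title, mw = res$mw,
                            hbd = res$hbd, hba = res$hba, pass = res$pass,
                            reasons = paste(res$reasons, collapse = ","))
  }
  if (!is.null(sdf_out)) write_sdf(kept, sdf_out)
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(title = character(), mw = numeric(), hbd = integer(),
               hba = integer(), pass = logical(), reasons = character())
  if (!is.null(report_out)) write_table(report, report_out)
  fb <- table(factor(reasons_all,
                     levels = c("mw_below", "mw_above", "hbd_above",
                                "hba_below", "hba_above", "parse_error")))
  list(read = length(poses), passed = length(kept),
       failed = length(poses) - length(kept),
       failed_by_reason = stats::setNames(as.integer(fb), names(fb)),
       report = report)
}
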