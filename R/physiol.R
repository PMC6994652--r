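#' Relative electrical conductance (REC)
#'
#' REC = (R1 / R2) x 100, where R1 is the initial conductivity of the
#' leaf extraction solution and R2 the final conductivity after boiling.
#' A membrane-damage proxy under chilling stress; scale-invariant in the
#' instrument units. R1 outside `[0, R2]` is physiologically unexpected
#' and triggers a warning but is still computed.
#'
#' @param r1,r2 initial and final conductivity (same units; `r2 > 0`).
#' @return REC percentage(s).
#' @export
rec_percent <- function(r1, r2) {
  if (any(r2 <= 0)) stop("final conductivity R2 must be > 0")
  if (any(r1 < 0 | r1 > r2))
    warning("R1 outside the expected range [0, R2]")
  (r1 / r2) * 100
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator)`.
#' No amplification is encoded as `NA` (an explicit marker, never a
#' sentinel cycle number): a calibrator target that does not amplify
#' yields the infinite-ratio marker (`Inf`, status `"infinite"`); a sample
#' target that does not amplify while the calibrator does yields 0 with
#' status `"below_detection"`.
#'
#' @param ct_target,ct_reference sample Ct of the target and reference
#'   genes (`NA` = no amplification).
#' @param calib_target,calib_reference calibrator Ct values.
#' @return a `relative_expression`: list with `value` and `status`
#'   (`"ok"`, `"infinite"`, `"below_detection"` or `"undetermined"`).
#' @export
ddct_expression <- function(ct_target, ct_reference, calib_target,
                            calib_reference) {
  if (is.na(ct_reference) || is.na(calib_reference))
    stop("reference-gene Ct values must amplify")
  if (is.na(ct_target) && is.na(calib_target))
    return(structure(list(value = NA_real_, status = "undetermined"),
                     class = "relative_expression"))
  if (is.na(calib_target))
    return(structure(list(value = Inf, status = "infinite"),
                     class = "relative_expression"))
  if (is.na(ct_target))
    return(structure(list(value = 0, status = "below_detection"),
                     class = "relative_expression"))
  ddct <- (ct_target - ct_reference) - (calib_target - calib_reference)
  structure(list(value = 2^(-ddct), status = "ok"),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat("relative expression:", format(x$value), sprintf("[%s]", x$status),
      "\n")
  invisible(x)
}

#' Mobility verdict from heterograft vs negative-control expression
#'
#' A predicted mobile transcript is `supported` when the heterograft to
#' negative-control expression ratio exceeds `min_fold`, or when the
#' negative control does not amplify while the heterograft does;
#' `refuted` when the heterograft shows no expression or the negative
#' control shows comparable/high expression; `indeterminate` when neither
#' amplifies.
#'
#' @param hetero_expr,negctrl_expr `relative_expression` objects (or bare
#'   numerics) for the heterograft sample and the negative control.
#' @param min_fold ratio that must be exceeded for support (default 2).
#' @return one of `"supported"`, `"refuted"`, `"indeterminate"`.
#' @export
mobility_ratio <- function(hetero_expr, negctrl_expr, min_fold = 2) {
  val <- function(x) if (inherits(x, "relative_expression")) x$value else x
  st <- function(x) if (inherits(x, "relative_expression")) x$status
        else "ok"
  h <- val(hetero_expr); n <- val(negctrl_expr)
  h_dead <- (!is.na(h) && h == 0) || st(hetero_expr) == "below_detection"
  n_dead <- (!is.na(n) && n == 0) || st(negctrl_expr) == "below_detection"
  if (h_dead && n_dead) return("indeterminate")
  if (h_dead) return("refuted")
  if (n_dead || is.infinite(h)) return("supported")
  if (is.na(h) || is.na(n)) return("indeterminate")
  if (h / n > min_fold) "supported" else "refuted"
}

#' Read a physiology measurement table and compute per-gene verdicts
#'
#' Input is a TSV with one row per qPCR well: `sample_id`, `gene_id`,
#' `ct_target`, `ct_reference`, `group` (one of `heterograft`,
#' `positive-control`, `negative-control`), `replicate`. Empty cells mark
#' no amplification. Replicate Ct values are averaged before the ddCt
#' computation (all-`NA` groups stay no-amplification); the positive
#' control is the calibrator.
#'
#' @param path measurements TSV.
#' @param min_fold see [mobility_ratio()].
#' @return per-gene data frame with expression ratios and verdicts.
#' @export
qpcr_verdicts <- function(path, min_fold = 2) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "ct_target", "ct_reference", "group")
  stopifnot(all(need %in% names(m)))
  out <- list()
  for (g in unique(m$gene_id)) {
    sub <- m[m$gene_id == g, , drop = FALSE]
    avg <- function(grp, col) {
      v <- sub[[col]][sub$group == grp]
      if (length(v) == 0L || all(is.na(v))) NA_real_
      else mean(v, na.rm = TRUE)
    }
    het <- ddct_expression(avg("heterograft", "ct_target"),
                           avg("heterograft", "ct_reference"),
                           avg("positive-control", "ct_target"),
                           avg("positive-control", "ct_reference"))
    neg <- ddct_expression(avg("negative-control", "ct_target"),
                           avg("negative-control", "ct_reference"),
                           avg("positive-control", "ct_target"),
                           avg("positive-control", "ct_reference"))
    out[[g]] <- data.frame(
      gene_id = g, hetero_expr = het$value, hetero_status = het$status,
      negctrl_expr = neg$value, negctrl_status = neg$status,
      verdict = mobility_ratio(het, neg, min_fold),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
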