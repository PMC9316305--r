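#' Log reduction value of an impurity
#'
#' LRV = log10(feed concentration / eluate concentration), using matched
#' units (here ppm = ng impurity per mg product, the convention for host
#' cell protein, host cell DNA and leached protein A alike). A positive LRV
#' means the impurity was reduced across the step. An eluate below the
#' assay's detection limit is handled by substituting the limit: the result
#' is then a lower bound, flagged via the `"censored"` attribute and a
#' message.
#'
#' @param feed_ppm Impurity level in the feed (> 0).
#' @param eluate_ppm Impurity level in the eluate (>= 0; 0 means below
#'   detection).
#' @param detection_limit Assay detection limit (ppm) substituted when
#'   `eluate_ppm` is 0.
#' @return LRV in log10 units; attribute `censored = TRUE` when the
#'   detection limit was substituted.
#' @examples
#' lrv(54004, 341.3)  # ~2.2
#' @export
lrv <- function(feed_ppm, eluate_ppm, detection_limit = NULL) {
  check_number(feed_ppm, "feed_ppm", positive = TRUE)
  check_number(eluate_ppm, "eluate_ppm", nonneg = TRUE)
  if (eluate_ppm == 0) {
    if (is.null(detection_limit)) {
      cs_abort(paste("Eluate below detection: supply `detection_limit` to",
                     "report a lower-bound LRV."), "invalid_parameter")
    }
    check_number(detection_limit, "detection_limit", positive = TRUE)
    message(sprintf(
      "Eluate below detection; reporting LRV >= log10(%g/%g) with the limit substituted.",
      feed_ppm, detection_limit))
    return(structure(log10(feed_ppm / detection_limit), censored = TRUE))
  }
  log10(feed_ppm / eluate_ppm)
}

#' Step yield from load and pool masses
#'
#' Eluted over loaded product mass. Values slightly above 1 are tolerated
#' (assay noise); above 1.05 the inputs are rejected as implausible.
#'
#' @param load_mass_g Product mass applied (> 0).
#' @param eluted_mass_g Product mass recovered in the pool (>= 0).
#' @return Yield fraction.
#' @export
step_yield <- function(load_mass_g, eluted_mass_g) {
  check_number(load_mass_g, "load_mass_g", positive = TRUE)
  check_number(eluted_mass_g, "eluted_mass_g", nonneg = TRUE)
  y <- eluted_mass_g / load_mass_g
  if (y > 1.05) {
    cs_abort(sprintf("Yield %.3f exceeds 1.05: implausible mass balance.", y),
             "implausible_yield")
  }
  y
}

#' Per-cycle product-quality record
#'
#' @param yield Step yield fraction in \[0, 1\].
#' @param monomer_fraction Monomer fraction in \[0, 1\].
#' @param hcp_lrv,hcdna_lrv Impurity log reduction values (finite).
#' @param leached_proa_ppm Leached protein A, ng per mg product (>= 0).
#' @return A one-row data.frame of class `quality_record`.
#' @export
quality_record <- function(yield, monomer_fraction = NA_real_,
                           hcp_lrv = NA_real_, hcdna_lrv = NA_real_,
                           leached_proa_ppm = NA_real_) {
  for (f in c(yield = yield, monomer_fraction = monomer_fraction)) {
    if (!is.na(f) && (f < 0 || f > 1)) {
      cs_abort("Fractions must lie in [0, 1].", "invalid_parameter")
    }
  }
  if (!is.na(leached_proa_ppm) && leached_proa_ppm < 0) {
    cs_abort("`leached_proa_ppm` must be >= 0.", "invalid_parameter")
  }
  structure(
    data.frame(yield = yield, monomer_fraction = monomer_fraction,
               hcp_lrv = hcp_lrv, hcdna_lrv = hcdna_lrv,
               leached_proa_ppm = leached_proa_ppm),
    class = c("quality_record", "data.frame")
  )
}

QUALITY_COLS <- c("cycle", "yield", "monomer_fraction", "hcp_lrv",
                  "hcdna_lrv", "leached_proa_ppm")

#' Read / write per-cycle quality tables
#'
#' CSV with columns `cycle, yield, monomer_fraction, hcp_lrv, hcdna_lrv,
#' leached_proa_ppm` (the sampling scheme where every n-th elution pool is
#' assayed).
#'
#' @param path File path.
#' @return `read_quality_table`: a validated data.frame.
#' @export
read_quality_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(QUALITY_COLS, names(df))
  if (length(missing)) {
    cs_abort(sprintf("%s: missing column(s) %s.", path,
                     paste(missing, collapse = ", ")), "format_error")
  }
  df
}

#' @rdname read_quality_table
#' @param x Data.frame with the quality columns.
#' @export
write_quality_table <- function(x, path) {
  stopifnot(all(QUALITY_COLS %in% names(x)))
  utils::write.csv(x[QUALITY_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
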