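#' Cholesterol-lowering medications recognized by the medication-use rule
#'
#' Statins are matched by the substring "statin"; all other agents are
#' matched by name (case-insensitive).
#' @return Character vector of medication names / name patterns.
#' @export
cholesterol_lowering_medications <- function() {
  c("statin", "gemfibrozil", "fenofibrate", "clofibrate", "bempedoic acid",
    "ezetimibe", "cholestyramine", "colestipol", "colesevelam",
    "alirocumab", "evolocumab")
}

.order_statuses <- c("Sent", "Dispensed", "Verified", "Discontinued")

validate_orders <- function(orders) {
  assert_cols(orders, c("id", "medication", "status", "year"),
              "medication-order table")
  bad <- setdiff(unique(orders$status), .order_statuses)
  if (length(bad))
    stopf("unknown medication-order status: %s (expected %s)",
          paste(bad, collapse = ", "), paste(.order_statuses, collapse = "/"))
  invisible(orders)
}

#' Infer cholesterol-lowering medication use at a given year
#'
#' A subject is inferred to be on medication at \code{year} if some order with
#' status Sent, Dispensed or Verified was placed at or before \code{year} and
#' the medication was not discontinued before \code{year}. A discontinuation
#' is ignored when it was superseded: another qualifying order exists at or
#' after the discontinuation year and at or before \code{year}.
#'
#' @param orders data.frame with columns \code{id}, \code{medication},
#'   \code{status} (Sent/Dispensed/Verified/Discontinued), \code{year}.
#'   Orders for a single subject.
#' @param year integer year (same axis as the orders).
#' @return logical scalar (or vector if \code{year} has length > 1).
#' @export
infer_medication_use <- function(orders, year) {
  validate_orders(orders)
  qual <- orders$year[orders$status %in% c("Sent", "Dispensed", "Verified")]
  disc <- orders$year[orders$status == "Discontinued"]
  vapply(year, function(yr) {
    q <- qual[qual <= yr]
    if (!length(q)) return(FALSE)
    d <- disc[disc < yr]
    if (!length(d)) return(TRUE)
    # every earlier discontinuation must be superseded by a later order
    all(vapply(d, function(dd) any(q >= dd), logical(1)))
  }, logical(1))
}

#' Derive LDL-C, non-HDL-C and log-triglycerides from a lipid panel
#'
#' non-HDL-C = TC - HDL-C. LDL-C uses the recorded value when available and
#' otherwise the Friedewald estimate TC - HDL-C - TG/5 (mg/dl), valid only
#' for TG <= 400 mg/dl; above that bound with no recorded LDL-C the value is
#' returned missing. Triglycerides are natural-log transformed. Records with
#' HDL-C >= TC are flagged invalid (derived values still returned).
#'
#' @param tc,hdl,tg numeric vectors, mg/dl.
#' @param ldl_recorded optional numeric vector of recorded LDL-C, mg/dl
#'   (NA where absent).
#' @return data.frame with columns \code{ldl}, \code{non_hdl}, \code{ln_tg},
#'   \code{valid}.
#' @export
derive_lipids <- function(tc, hdl, tg, ldl_recorded = NULL) {
  n <- length(tc)
  if (is.null(ldl_recorded)) ldl_recorded <- rep(NA_real_, n)
  stopifnot(length(hdl) == n, length(tg) == n, length(ldl_recorded) == n)
  if (any(tc <= 0 | hdl <= 0 | tg <= 0, na.rm = TRUE))
    stopf("lipid concentrations must be positive")
  non_hdl <- tc - hdl
  friedewald <- ifelse(tg <= 400, tc - hdl - tg / 5, NA_real_)
  ldl <- ifelse(is.na(ldl_recorded), friedewald, ldl_recorded)
  data.frame(ldl = ldl, non_hdl = non_hdl, ln_tg = log(tg),
             valid = !is.na(tc) & !is.na(hdl) & hdl < tc)
}

icd_prefix_table <- function() {
  path <- system.file("extdata", "icd_comorbidity_prefixes_v1.tsv",
                      package = "lipidtraj")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Comorbidity flags from ICD-9/ICD-10 code lists
#'
#' Codes are matched by string prefix after stripping dots, against versioned
#' prefix lists for hypertension, atherosclerosis, cerebrovascular disease,
#' diabetes, ischemic heart disease / myocardial infarction, and malignant
#' neoplasm. Unmatched codes are ignored.
#'
#' @param icd_codes character vector of ICD codes (dots allowed).
#' @return named logical vector, one element per condition.
#' @export
comorbidity_flags <- function(icd_codes) {
  tab <- icd_prefix_table()
  conditions <- c("hypertension", "atherosclerosis", "cerebrovascular",
                  "diabetes", "ihd_mi", "malignancy")
  codes <- gsub(".", "", toupper(icd_codes), fixed = TRUE)
  out <- vapply(conditions, function(cond) {
    prefixes <- tab$prefix[tab$condition == cond]
    any(vapply(codes, function(cd) any(startsWith(cd, prefixes)), logical(1)))
  }, logical(1))
  names(out) <- conditions
  out
}

#' Inclusion filter: at least three measured years within the window
#'
#' Retains subjects with measurements in at least three distinct relative
#' years within \code{window} (default -10..0, the 11-year window ending at
#' the index year).
#'
#' @param measurements data.frame with columns \code{id}, \code{rel_year}.
#' @param min_years minimum number of distinct measured years (default 3).
#' @param window integer vector of admissible relative years.
#' @return vector of eligible subject ids.
#' @export
apply_inclusion_filter <- function(measurements, min_years = 3L,
                                   window = -10:0) {
  assert_cols(measurements, c("id", "rel_year"), "measurement table")
  m <- measurements[measurements$rel_year %in% window, ]
  yrs <- tapply(m$rel_year, m$id, function(v) length(unique(v)))
  names(yrs)[!is.na(yrs) & yrs >= min_years]
}

#' Aggregate raw lipid measurements to one record per subject-year
#'
#' Multiple same-year values of a lipid are averaged before any
#' transformation; the on-medication flag for a year is true if any
#' measurement that year was on medication. The annual TC/HDL/TG means are
#' then passed through \code{\link{derive_lipids}} to add non-HDL-C, LDL-C
#' and ln(TG).
#'
#' @param measurements long data.frame with columns \code{id},
#'   \code{rel_year}, \code{lipid} (one of "tc", "hdl", "tg", "ldl"),
#'   \code{value}, \code{on_med}.
#' @return data.frame with one row per subject-year: \code{id},
#'   \code{rel_year}, \code{tc}, \code{hdl}, \code{tg}, \code{ldl},
#'   \code{non_hdl}, \code{ln_tg}, \code{on_med}.
#' @export
aggregate_annual <- function(measurements) {
  assert_cols(measurements, c("id", "rel_year", "lipid", "value", "on_med"),
              "measurement table")
  agg <- stats::aggregate(value ~ id + rel_year + lipid, data = measurements,
                          FUN = mean)
  med <- stats::aggregate(on_med ~ id + rel_year, data = measurements,
                          FUN = any)
  wide <- stats::reshape(agg, idvar = c("id", "rel_year"),
                         timevar = "lipid", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (cc in c("tc", "hdl", "tg", "ldl"))
    if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  out <- merge(wide, med, by = c("id", "rel_year"))
  der <- derive_lipids(out$tc, out$hdl, out$tg, out$ldl)
  out$ldl <- der$ldl
  out$non_hdl <- der$non_hdl
  out$ln_tg <- der$ln_tg
  out$valid <- der$valid
  out[order(out$id, out$rel_year),
      c("id", "rel_year", "tc", "hdl", "tg", "ldl", "non_hdl", "ln_tg",
        "on_med", "valid")]
}

#' Standardize scores to mean 0 and sample SD 1
#'
#' Used for polygenic scores, standardized within each case/control cohort so
#' effect sizes are comparable across scores.
#'
#' @param scores numeric vector (length >= 2, non-constant).
#' @return standardized numeric vector.
#' @export
standardize_scores <- function(scores) {
  if (length(scores) < 2L) stopf("need at least two scores to standardize")
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stopf("scores are constant; cannot standardize")
  (scores - mean(scores)) / s
}
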