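#' Convert a raw antibody level to multiples of the upper limit of normal
#'
#' @param raw_level Nonnegative raw assay value(s).
#' @param uln Assay-specific upper limit of normal (positive).
#' @return `raw_level / uln`. A value above 1 is a positive test.
#' @examples
#' to_mULN(2.5, uln = 0.5)
#' @export
to_mULN <- function(raw_level, uln) {
  if (!is.numeric(uln) || any(uln <= 0)) stop_input("'uln' must be > 0")
  if (any(raw_level < 0, na.rm = TRUE)) stop_input("'raw_level' must be >= 0")
  raw_level / uln
}

#' Natural log of an mULN level with a positivity-agnostic floor
#'
#' All levels enter the prediction models on the natural-log scale, whether or
#' not they exceed the positivity threshold; a small floor keeps the transform
#' defined at zero.
#'
#' @param mULN Nonnegative level(s) in multiples of the upper limit of normal.
#' @param floor Positive lower bound applied before the log (default 0.01).
#' @return `log(pmax(mULN, floor))`.
#' @export
log_level <- function(mULN, floor = 0.01) {
  check_scalar(floor, "floor", 0, strict_lower = TRUE)
  log(pmax(mULN, floor))
}

#' Detect seroconversion for one antibody
#'
#' Seroconversion is the first appearance of a positive result (mULN > 1) in
#' two consecutive recorded samples of the same antibody, regardless of the
#' time between them. The first visit of the pair is the initial visit, the
#' second the confirmatory visit.
#'
#' @param levels Age-ordered mULN series for one child and one antibody;
#'   `NA` counts as not positive.
#' @param threshold Positivity threshold, strict (default 1).
#' @return Integer vector `c(initial, confirmatory)` of indices into
#'   `levels`, or `NULL` when no consecutive positive pair exists.
#' @examples
#' detect_seroconversion_antibody(c(0.5, 2.0, 3.0))  # c(2, 3)
#' @export
detect_seroconversion_antibody <- function(levels, threshold = 1) {
  pos <- !is.na(levels) & levels > threshold
  if (length(pos) < 2L) return(NULL)
  hit <- which(pos[-length(pos)] & pos[-1])
  if (!length(hit)) return(NULL)
  c(hit[1L], hit[1L] + 1L)
}

#' Build the per-child seroconversion record
#'
#' Applies [detect_seroconversion_antibody()] to each of IAA, GADA and IA-2A
#' using only visits strictly before diagnosis, then anchors the child-level
#' initial/confirmatory visits at the antibody whose confirmatory visit is
#' earliest (ties: earliest initial visit, then the fixed order IAA, GADA,
#' IA-2A). Children with no confirmed seroconversion before diagnosis, or with
#' a missing level for any antibody at either anchoring visit, are excluded.
#'
#' @param child One-row data.frame with at least `child_id`,
#'   `diagnosis_age_years`, `last_followup_age_years`.
#' @param visits Age-ordered visits of that child (`age_years`, `iaa_mULN`,
#'   `gada_mULN`, `ia2a_mULN`).
#' @param threshold Positivity threshold (strict; default 1).
#' @return One-row data.frame (see [seroconversion_records()]) or `NULL` when
#'   the child is excluded.
#' @export
build_seroconversion_record <- function(child, visits, threshold = 1) {
  stopifnot(nrow(child) == 1L)
  if (!is.na(child$diagnosis_age_years)) {
    visits <- visits[visits$age_years < child$diagnosis_age_years, , drop = FALSE]
  }
  if (nrow(visits) < 2L) return(NULL)
  if (is.unsorted(visits$age_years, strictly = TRUE)) {
    stop_input("visits of child ", child$child_id,
               " are not strictly increasing in age")
  }
  pairs <- lapply(ANTIBODIES, function(ab) {
    detect_seroconversion_antibody(visits[[paste0(ab, "_mULN")]], threshold)
  })
  names(pairs) <- ANTIBODIES
  found <- !vapply(pairs, is.null, logical(1))
  if (!any(found)) return(NULL)

  cand <- which(found)
  conf_age <- vapply(cand, function(j) visits$age_years[pairs[[j]][2]], numeric(1))
  init_age <- vapply(cand, function(j) visits$age_years[pairs[[j]][1]], numeric(1))
  ord <- order(conf_age, init_age, cand)  # fixed antibody order breaks final ties
  win <- cand[ord[1L]]
  idx <- pairs[[win]]

  lev <- function(ab, k) visits[[paste0(ab, "_mULN")]][idx[k]]
  levs_init <- vapply(ANTIBODIES, lev, numeric(1), k = 1L)
  levs_conf <- vapply(ANTIBODIES, lev, numeric(1), k = 2L)
  if (anyNA(levs_init) || anyNA(levs_conf)) return(NULL)

  out <- data.frame(
    child_id = child$child_id,
    antibody = toupper(ANTIBODIES[win]),
    age_initial = visits$age_years[idx[1]],
    age_confirm = visits$age_years[idx[2]],
    stringsAsFactors = FALSE
  )
  for (j in seq_along(ANTIBODIES)) {
    ab <- ANTIBODIES[j]
    out[[paste0(ab, "_mULN_init")]] <- levs_init[j]
    out[[paste0(ab, "_mULN_conf")]] <- levs_conf[j]
    out[[paste0("pos_", ab, "_init")]] <- levs_init[j] > threshold
    out[[paste0("pos_", ab, "_conf")]] <- levs_conf[j] > threshold
    pr <- pairs[[ab]]
    out[[paste0(ab, "_age_init")]] <- if (is.null(pr)) NA_real_ else visits$age_years[pr[1]]
    out[[paste0(ab, "_age_conf")]] <- if (is.null(pr)) NA_real_ else visits$age_years[pr[2]]
  }
  out
}

#' Seroconversion records for a whole cohort
#'
#' @param children Child-level data.frame (`child_id`, `diagnosis_age_years`,
#'   `last_followup_age_years`, covariates).
#' @param visits Visit-level data.frame for all children.
#' @param threshold Positivity threshold (strict; default 1).
#' @return data.frame with one row per retained (confirmed, complete) child:
#'   defining `antibody`, child-level `age_initial` / `age_confirm`, the three
#'   antibodies' mULN levels and positivity flags at both visits, and each
#'   antibody's own initial/confirmatory ages (NA when never confirmed).
#' @seealso [build_seroconversion_record()]
#' @export
seroconversion_records <- function(children, visits, threshold = 1) {
  split_visits <- split(visits, visits$child_id)
  recs <- lapply(seq_len(nrow(children)), function(i) {
    vv <- split_visits[[children$child_id[i]]]
    if (is.null(vv)) return(NULL)
    build_seroconversion_record(children[i, , drop = FALSE],
                                vv[order(vv$age_years), , drop = FALSE],
                                threshold)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    out <- build_seroconversion_record(
      data.frame(child_id = "x", diagnosis_age_years = NA_real_,
                 last_followup_age_years = 1),
      data.frame(age_years = c(0, 0.5), iaa_mULN = c(2, 2),
                 gada_mULN = c(0, 0), ia2a_mULN = c(0, 0)))
    return(out[0, , drop = FALSE])
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
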