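# Substrate-specificity calling: match SDP residues against the typical
# transporter patterns, with near-match (single-mismatch) reporting, plus
# data-driven ar/R annotation rules.

#' Match nine SDP residues against a substrate pattern
#'
#' Position-by-position set membership. A gap (NA) at an SDP counts as a
#' mismatch, never as a wildcard. The call is `FULL` on nine matches, `NEAR`
#' on at most `near_max` mismatches, otherwise `NO`.
#'
#' @param sdp character vector of nine residues (NA allowed for gaps), or an
#'   `aqp_profile` (its `sdp` slot is used).
#' @param pattern one pattern from [load_patterns()].
#' @param near_max maximum mismatches still called `NEAR` (default one: the
#'   family's described novel-type variants are single-position deviations).
#' @param query_id id carried into the report.
#' @return An `aqp_match` list: `query_id`, `substrate`, `pattern_class`,
#'   `n_match`, `call`, `mismatches` (data.frame of position label, observed
#'   residue, allowed set).
#' @export
match_pattern <- function(sdp, pattern, near_max = 1L, query_id = NULL) {
  if (inherits(sdp, "aqp_profile")) {
    query_id <- query_id %||% sdp$query_id
    sdp <- sdp$sdp
  }
  sdp <- as.character(sdp)
  if (length(sdp) != 9L) stop("profile must provide nine SDP residues")
  ok <- vapply(1:9, function(i)
    !is.na(sdp[i]) && sdp[i] %in% pattern$allowed[[i]], logical(1))
  n_match <- sum(ok)
  bad <- which(!ok)
  mism <- data.frame(
    position = sprintf("SDP%d", bad),
    observed = ifelse(is.na(sdp[bad]), "gap", sdp[bad]),
    allowed = vapply(pattern$allowed[bad], paste, character(1), collapse = "/"),
    stringsAsFactors = FALSE)
  call <- if (n_match == 9L) "FULL" else if (9L - n_match <= near_max) "NEAR" else "NO"
  structure(list(query_id = query_id %||% "query",
                 substrate = pattern$substrate,
                 pattern_class = pattern$class %||% "typical",
                 n_match = n_match, call = call, mismatches = mism),
            class = "aqp_match")
}

#' Substrate calls for a set of profiles
#'
#' Matches every profile against every pattern and tabulates the reports;
#' FULL calls per substrate are summarized in the `"summary"` attribute.
#'
#' @param profiles list of `aqp_profile` objects (or nine-residue vectors,
#'   named by query).
#' @param patterns list from [load_patterns()].
#' @param near_max forwarded to [match_pattern()].
#' @return data.frame with one row per (profile, pattern): `query_id`,
#'   `substrate`, `pattern_class`, `call`, `n_match`, `mismatches`
#'   (comma-joined position labels).
#' @export
call_substrates <- function(profiles, patterns = load_patterns(),
                            near_max = 1L) {
  if (length(profiles) == 0L) {
    out <- data.frame(query_id = character(), substrate = character(),
                      pattern_class = character(), call = character(),
                      n_match = integer(), mismatches = character(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- setNames(integer(0), character(0))
    return(out)
  }
  rows <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    qid <- if (inherits(p, "aqp_profile")) p$query_id else
      names(profiles)[k] %||% paste0("profile", k)
    for (pat in patterns) {
      m <- match_pattern(p, pat, near_max = near_max, query_id = qid)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = m$query_id, substrate = m$substrate,
        pattern_class = m$pattern_class, call = m$call, n_match = m$n_match,
        mismatches = paste(m$mismatches$position, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  full <- out[out$call == "FULL", ]
  attr(out, "summary") <- table(factor(full$substrate,
                                       levels = unique(out$substrate)))
  out
}

#' Substrate calls on the curated printed SDP residues
#'
#' SDP positions are substrate-specific, so the curated table prints one
#' nine-residue set per (protein, substrate) heading. Every printed row is
#' matched against every pattern; the row's own heading is kept alongside so
#' the table's internal consistency can be checked.
#'
#' @param observations data.frame from [load_sdp_observations()].
#' @param patterns list from [load_patterns()] (include the novel patterns to
#'   reproduce the described novel-type assignments).
#' @param near_max forwarded to [match_pattern()].
#' @return data.frame: `label`, `row_substrate` (heading the residues were
#'   printed under), `substrate` (pattern matched), `pattern_class`, `call`,
#'   `n_match`, `mismatches`.
#' @export
call_printed_sdps <- function(observations = load_sdp_observations(),
                              patterns = load_patterns(include_novel = TRUE),
                              near_max = 1L) {
  sdp_cols <- paste0("sdp", 1:9)
  rows <- list()
  for (i in seq_len(nrow(observations))) {
    sdp <- as.character(observations[i, sdp_cols])
    for (pat in patterns) {
      m <- match_pattern(sdp, pat, near_max = near_max,
                         query_id = observations$label[i])
      rows[[length(rows) + 1L]] <- data.frame(
        label = observations$label[i],
        row_substrate = observations$substrate[i],
        substrate = m$substrate, pattern_class = m$pattern_class,
        call = m$call, n_match = m$n_match,
        mismatches = paste(m$mismatches$position, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Load the registered ar/R annotation rules
#'
#' Rules are data, not code: each names the residue predicate (ar/R quartet,
#' optionally the two NPA triplets) and the annotation it implies.
#'
#' @param path JSON rules file.
#' @return List of rules.
#' @export
load_arr_rules <- function(path = aqp_extdata("arr_rules.json")) {
  read_json(path, simplifyVector = FALSE)
}

#' Apply ar/R annotation rules to a profile
#'
#' Fires every registered rule whose residue predicate holds for the
#' profile's ar/R quartet and NPA triplets.
#'
#' @param profile `aqp_profile`.
#' @param rules list from [load_arr_rules()].
#' @return data.frame of fired rules: `query_id`, `rule_id`, `note`.
#' @export
apply_arr_rules <- function(profile, rules = load_arr_rules()) {
  arr <- paste(ifelse(is.na(profile$arr), "gap", profile$arr), collapse = "-")
  fired <- Filter(function(rule) {
    if (!is.null(rule$arr) && rule$arr != arr) return(FALSE)
    if (!is.null(rule$npa_lb) &&
        (is.na(profile$npa_lb) || rule$npa_lb != profile$npa_lb)) return(FALSE)
    if (!is.null(rule$npa_le) &&
        (is.na(profile$npa_le) || rule$npa_le != profile$npa_le)) return(FALSE)
    TRUE
  }, rules)
  data.frame(query_id = rep(profile$query_id, length(fired)),
             rule_id = vapply(fired, `[[`, character(1), "id"),
             note = vapply(fired, `[[`, character(1), "note"),
             stringsAsFactors = FALSE)
}
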