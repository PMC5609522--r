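pattern_by <- function(patterns, substrate, class = "typical") {
  for (p in patterns)
    if (p$substrate == substrate && p$class == class) return(p)
  stop("no such pattern")
}

test_that("pattern matching reproduces the printed worked examples", {
  pats <- load_patterns(include_novel = TRUE)
  # a PIP1-type urea row matches the urea signature in full
  m <- match_pattern(c("H", "P", "F", "L", "L", "P", "G", "G", "N"),
                     pattern_by(pats, "urea"), query_id = "BvPIP1;2")
  expect_equal(m$call, "FULL")
  expect_equal(m$n_match, 9L)
  expect_equal(nrow(m$mismatches), 0L)
  # the NIP1 ammonia row misses only at SDP2 (H where K/L/N/V is expected)
  m2 <- match_pattern(c("F", "H", "F", "T", "A", "D", "L", "E", "T"),
                      pattern_by(pats, "NH3"), query_id = "BvNIP1;1")
  expect_equal(m2$call, "NEAR")
  expect_equal(m2$mismatches$position, "SDP2")
  expect_equal(m2$mismatches$observed, "H")
  expect_false("H" %in% strsplit(m2$mismatches$allowed, "/")[[1]])
  # a universal pattern accepts anything
  universal <- list(substrate = "any", class = "typical",
                    allowed = replicate(9, aqpkit:::AA_ALPHABET,
                                        simplify = FALSE))
  expect_equal(match_pattern(sample(aqpkit:::AA_ALPHABET, 9), universal)$call,
               "FULL")
  # a gap is a mismatch, never a wildcard
  g <- c("H", NA, "F", "L", "L", "P", "G", "G", "N")
  mg <- match_pattern(g, pattern_by(pats, "urea"))
  expect_equal(mg$call, "NEAR")
  expect_equal(mg$mismatches$observed, "gap")
})

test_that("pattern matching equals the brute-force oracle on random input", {
  pats <- load_patterns()
  set.seed(61)
  for (i in 1:1000) {
    sdp <- sample(aqpkit:::AA_ALPHABET, 9, replace = TRUE)
    if (runif(1) < 0.1) sdp[sample(9, 1)] <- NA
    pat <- pats[[sample(length(pats), 1)]]
    m <- match_pattern(sdp, pat)
    expect_identical(m$n_match, oracle_match_count(sdp, pat$allowed))
    expect_identical(m$call == "FULL", m$n_match == 9L)
    expect_equal(nrow(m$mismatches), 9L - m$n_match)
  }
})

test_that("shrinking an allowed set never improves a call", {
  pats <- load_patterns()
  set.seed(67)
  rank <- c(NO = 0, NEAR = 1, FULL = 2)
  for (i in 1:100) {
    pat <- pats[[sample(length(pats), 1)]]
    sdp <- sample(aqpkit:::AA_ALPHABET, 9, replace = TRUE)
    before <- match_pattern(sdp, pat)$call
    k <- sample(9, 1)
    if (length(pat$allowed[[k]]) > 1) {
      pat$allowed[[k]] <- pat$allowed[[k]][-1]
      after <- match_pattern(sdp, pat)$call
      expect_lte(rank[[after]], rank[[before]])
    }
  }
})

test_that("printed residue rows reproduce the family's substrate assignments", {
  calls <- call_printed_sdps()
  own <- calls[calls$row_substrate == calls$substrate &
                 calls$pattern_class == "typical", ]
  tally <- table(own$row_substrate, own$call)
  # urea: 22 printed rows, 20 exact matches plus two single-residue
  # deviations at SDP6 (printed table's own internal variance)
  expect_equal(sum(own$row_substrate == "urea"), 22L)
  expect_equal(unname(tally["urea", "FULL"]), 20L)
  urea_near <- own[own$row_substrate == "urea" & own$call == "NEAR", ]
  expect_setequal(urea_near$label, c("BvTIP4;1", "BvNIP4;2"))
  expect_true(all(urea_near$mismatches == "SDP6"))
  expect_equal(unname(tally["boric_acid", "FULL"]), 5L)
  expect_equal(unname(tally["H2O2", "FULL"]), 7L)
  # the CO2 rows deviate from the typical signature at two positions each,
  # and the single ammonia row at one (SDP2)
  expect_lte(sum(own$row_substrate == "CO2" & own$call == "FULL"), 3L)
  expect_lte(sum(own$row_substrate == "NH3" & own$call == "FULL"), 1L)
  # every listed row is FULL or a near-miss against a typical-or-novel
  # pattern of its heading
  all_calls <- calls[calls$row_substrate == calls$substrate, ]
  best <- tapply(all_calls$n_match, all_calls$label, max)
  expect_true(all(best >= 8L))
  # nothing matches the silicic-acid signature
  expect_equal(sum(calls$substrate == "silicic_acid" &
                     calls$call == "FULL"), 0L)
})

test_that("novel-type patterns capture the described variant transporters", {
  calls <- call_printed_sdps()
  nov <- calls[calls$pattern_class == "novel" &
                 calls$row_substrate == calls$substrate, ]
  expect_equal(nov$call[nov$label == "BvNIP1;1" & nov$substrate == "NH3"],
               "FULL")
  co2 <- nov[nov$substrate == "CO2", ]
  expect_setequal(co2$label, c("BvPIP1;2", "BvPIP1;3", "BvPIP2;1"))
  expect_true(all(co2$call %in% c("FULL", "NEAR")))
})

test_that("empty profile lists yield empty call tables", {
  out <- call_substrates(list())
  expect_equal(nrow(out), 0L)
})

test_that("ar/R annotation rules fire on their residue predicates", {
  rules <- load_arr_rules()
  mk_profile <- function(arr, lb = "NPA", le = "NPA") {
    structure(list(query_id = "q", npa_lb = lb, npa_le = le,
                   arr = setNames(arr, c("H2", "H5", "LE1", "LE2")),
                   froger = rep("A", 5), sdp = rep("A", 9)),
              class = "aqp_profile")
  }
  water <- apply_arr_rules(mk_profile(c("F", "H", "T", "R")), rules)
  expect_true("water_typical" %in% water$rule_id)
  form <- apply_arr_rules(mk_profile(c("H", "I", "G", "R")), rules)
  expect_true("formamide" %in% form$rule_id)
  boric <- apply_arr_rules(mk_profile(c("A", "I", "G", "R"), "NPS", "NPV"),
                           rules)
  expect_true("boric_acid_nip5_like" %in% boric$rule_id)
  # the boric rule needs the NPS/NPV pore, not just the filter
  none <- apply_arr_rules(mk_profile(c("A", "I", "G", "R")), rules)
  expect_false("boric_acid_nip5_like" %in% none$rule_id)
})
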