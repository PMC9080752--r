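refs <- study_reference_pigments()

test_that("every standard residue is classified exactly once", {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  cls <- classify_polarity(aas)
  expect_equal(length(cls), 20)
  expect_true(all(cls %in% c("polar", "nonpolar")))
  expect_equal(unname(cls[aas == "S"]), "polar")
  expect_equal(unname(cls[aas == "A"]), "nonpolar")
  expect_equal(sum(cls == "polar") + sum(cls == "nonpolar"), 20)
  expect_error(classify_polarity("X"), "X")
})

test_that("documented shifts are applied by exact (site, from, to) match", {
  tab <- tuning_sites()
  sh <- applicable_shifts(data.frame(bovine_site = 299, from = "S",
                                     to = "A"), "RH1", tab)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$shift_nm, -2)
  expect_equal(sh$rule, "documented")
  sh2 <- applicable_shifts(data.frame(bovine_site = 266, from = "T",
                                      to = "V"), "RH2", tab)
  expect_equal(sh2$shift_nm, -2)
  expect_equal(nrow(applicable_shifts(
    data.frame(bovine_site = integer(), from = character(),
               to = character()), "RH1", tab)), 0)
})

test_that("polarity matching borrows shifts only across a polarity change", {
  tab <- tuning_sites()
  # T266I is polar->nonpolar like the documented T266V row: shift borrowed
  sh <- applicable_shifts(data.frame(bovine_site = 266, from = "T",
                                     to = "I"), "RH2", tab)
  expect_equal(sh$rule, "polarity_matched")
  expect_equal(sh$shift_nm, -2)
  # T266S is polar->polar: no polarity change, no shift
  sh2 <- applicable_shifts(data.frame(bovine_site = 266, from = "T",
                                      to = "S"), "RH2", tab)
  expect_equal(nrow(sh2), 0)
  # substitution at an unknown site: nothing applied
  sh3 <- applicable_shifts(data.frame(bovine_site = 120, from = "S",
                                      to = "A"), "RH2", tab)
  expect_equal(nrow(sh3), 0)
})

test_that("ambiguous polarity matches are flagged, never averaged", {
  tab <- data.frame(opsin_class = "RH2", bovine_site = c(50, 50),
                    from = c("S", "T"), to = c("A", "G"),
                    shift_nm = c(-5, -9), source = "synthetic")
  sh <- applicable_shifts(data.frame(bovine_site = 50, from = "C",
                                     to = "V"), "RH2", tab)
  expect_equal(nrow(sh), 0)
  amb <- attr(sh, "ambiguous")
  expect_equal(amb$bovine_site, 50)
})

test_that("lambda-max predictions match the documented examples", {
  # RH1: 502 - 2 (S299A) = 500
  q <- make_opsin_variant(refs$RH1$sequence,
                          data.frame(bovine_site = 299, to = "A"))$sequence
  p <- predict_lambda_max(q, refs$RH1)
  expect_equal(p$predicted_lambda_max_nm, 500)
  expect_equal(p$applied$rule, "documented")
  # RH2A: 528 - 3 (C88A) + 1 (I112V) = 526
  q2 <- make_opsin_variant(refs$RH2Aalpha$sequence,
                           data.frame(bovine_site = c(88, 112),
                                      to = c("A", "V")))$sequence
  expect_equal(predict_lambda_max(q2, refs$RH2Aalpha)$predicted_lambda_max_nm,
               526)
  # LWS with no tuning-site differences stays at 560
  expect_equal(
    predict_lambda_max(refs$LWS$sequence, refs$LWS)$predicted_lambda_max_nm,
    560)
  # identical query: empty applied list
  p0 <- predict_lambda_max(refs$RH1$sequence, refs$RH1)
  expect_equal(p0$predicted_lambda_max_nm, 502)
  expect_equal(nrow(p0$applied), 0)
  expect_error(predict_lambda_max(
    opsin_sequence("q", "LWS", amino_acids = bovine_rhodopsin()),
    refs$RH1), "class mismatch")
})

test_that("prediction is additive, order-independent, and ledger-exact", {
  tab <- tuning_sites()
  plants <- data.frame(bovine_site = c(88, 112, 266),
                       to = c("C", "V", "V"))
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    q <- make_opsin_variant(refs$RH2B$sequence, plants[perm, ])$sequence
    p <- predict_lambda_max(q, refs$RH2B)
    # additivity is exact
    expect_identical(p$predicted_lambda_max_nm - p$reference_lambda_max_nm,
                     sum(p$applied$shift_nm))
    # planted shifts: M88C +3, I112V +1, T266V -2 -> 472 + 2
    expect_equal(p$predicted_lambda_max_nm, 474)
  }
})

test_that("paralogues differing by T266V are predicted 2 nm apart", {
  qa <- make_opsin_variant(refs$RH2B$sequence,
                           data.frame(bovine_site = 88, to = "C"))$sequence
  qb <- make_opsin_variant(refs$RH2B$sequence,
                           data.frame(bovine_site = c(88, 266),
                                      to = c("C", "V")))$sequence
  pa <- predict_lambda_max(qa, refs$RH2B)
  pb <- predict_lambda_max(qb, refs$RH2B)
  expect_equal(pa$predicted_lambda_max_nm - pb$predicted_lambda_max_nm, 2)
})

test_that("polarity candidates are flagged near known sites inside TM", {
  tab <- tuning_sites()
  # S166A: polar->nonpolar, in TM4, two sites from known RH1 site 164
  cand <- flag_polarity_candidates(
    data.frame(bovine_site = 166, from = "S", to = "A"), "RH1", tab)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$near_site, 164)
  # no polarity change: never flagged
  expect_equal(nrow(flag_polarity_candidates(
    data.frame(bovine_site = 166, from = "S", to = "T"), "RH1", tab)), 0)
  # outside every TM helix (site 345, C-terminal tail): never flagged
  tab2 <- rbind(tab, data.frame(opsin_class = "RH1", bovine_site = 344,
                                from = "T", to = "A", shift_nm = -1,
                                source = "synthetic"))
  expect_equal(nrow(flag_polarity_candidates(
    data.frame(bovine_site = 345, from = "T", to = "A"), "RH1", tab2)), 0)
  # proximity window is respected
  expect_equal(nrow(flag_polarity_candidates(
    data.frame(bovine_site = 170, from = "S", to = "A"), "RH1", tab,
    proximity = 2)), 0)
  expect_equal(nrow(flag_polarity_candidates(
    data.frame(bovine_site = 170, from = "S", to = "A"), "RH1", tab,
    proximity = 6)), 1)
})

test_that("candidates appear in predictions without moving the estimate", {
  q <- make_opsin_variant(refs$RH1$sequence,
                          data.frame(bovine_site = c(299, 166),
                                     to = c("A", "A")))$sequence
  p <- predict_lambda_max(q, refs$RH1)
  expect_equal(p$predicted_lambda_max_nm, 500)  # S166A adds no shift
  expect_true(166 %in% p$candidates$bovine_site)
})

test_that("the shipped tuning table loads and marker rows stay inert", {
  tab <- tuning_sites()
  expect_true(all(c("opsin_class", "bovine_site", "from", "to",
                    "shift_nm") %in% names(tab)))
  # marker rows (unquantified known sites) exist but are never applied
  markers <- tab[is.na(tab$shift_nm), ]
  expect_true(all(markers$bovine_site == 164))
  sh <- applicable_shifts(data.frame(bovine_site = 164, from = "A",
                                     to = "S"), "RH1", tab)
  expect_equal(nrow(sh), 0)
})
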