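test_that("lesion flags are extracted from representative karyotypes", {
  f <- parse_karyotype("46,XX,t(8;21)(q22;q22.1)[20]")
  expect_true(f$t_8_21)
  expect_equal(f$abnormality_count, 1L)
  expect_false(f$complex)

  f <- parse_karyotype("46,XY[20]")
  expect_true(f$normal)
  expect_true(all(!unlist(f[c("t_8_21", "inv16_or_t16_16", "complex",
                              "monosomal", "del5q_or_minus5", "minus7")])))

  f <- parse_karyotype("44,XY,-5,-7,del(17p)[18]")
  expect_true(f$del5q_or_minus5)
  expect_true(f$minus7)
  expect_true(f$minus17_or_abn17p)
  expect_equal(f$abnormality_count, 3L)
  expect_true(f$complex)
  expect_true(f$monosomal)

  # a single monosomy with no structural lesion is not monosomal
  f <- parse_karyotype("45,XY,-7[20]")
  expect_true(f$minus7)
  expect_false(f$monosomal)
  expect_false(f$complex)

  f <- parse_karyotype("49,XX,+8,+13,+21[20]")
  expect_true(f$hyperdiploid)
  expect_equal(f$abnormality_count, 3L)
  expect_true(f$complex)

  f <- parse_karyotype("46,XX,t(9;11)(p21.3;q23.3)[20]")
  expect_true(f$t_9_11)
  expect_false(f$t_v_11q23)
  f <- parse_karyotype("46,XY,t(4;11)(q21;q23)[20]")
  expect_true(f$t_v_11q23)
  f <- parse_karyotype("46,XY,t(v;11q23.3)[20]")
  expect_true(f$t_v_11q23)
  f <- parse_karyotype("46,XX,t(3;12)(q26.2;p13)[20]")
  expect_true(f$t_3q26_v)

  expect_error(parse_karyotype(""), "nonempty")
  expect_true(parse_karyotype("normal")$normal)
})

test_that("clone structure, loss of Y and constitutional lesions follow convention", {
  # clones are flattened to the union of abnormalities
  f <- parse_karyotype("46,XY,t(8;21)(q22;q22.1)[12]/46,XY,t(8;21)(q22;q22.1),del(9)(q22)[8]")
  expect_true(f$t_8_21)
  expect_equal(f$abnormality_count, 2L)
  # -Y and constitutional +21c do not count
  f <- parse_karyotype("45,X,-Y,t(8;21)(q22;q22.1)[20]")
  expect_equal(f$abnormality_count, 1L)
  f <- parse_karyotype("47,XY,+21c,t(9;22)(q34;q11.2)[20]")
  expect_equal(f$abnormality_count, 1L)
  expect_true(f$t_9_22)
  # unrecognized tokens are counted, not dropped
  expect_warning(f <- parse_karyotype("46,XY,weird(5)(q11)[20]"), "unrecognized")
  expect_equal(f$abnormality_count, 1L)
})

test_that("abnormality count matches a token-counting oracle on generated strings", {
  lesions <- c("t(8;21)(q22;q22.1)", "inv(16)(p13.1q22)", "del(5)(q13q33)",
               "-7", "+8", "t(9;22)(q34;q11.2)", "del(17)(p13)", "+21",
               "add(12)(p13)", "t(6;9)(p23;q34.1)")
  set.seed(99)
  for (rep in 1:30) {
    k <- sample(0:5, 1)
    toks <- sample(lesions, k)
    iscn <- paste(c("46,XY", toks), collapse = ",")
    f <- parse_karyotype(paste0(iscn, "[20]"))
    expect_equal(f$abnormality_count, k)
    expect_equal(f$normal, k == 0L)
  }
})

test_that("adverse cytogenetics applies the edition-specific lesion sets", {
  cplx <- parse_karyotype("44,XY,-5,-7,del(17p)[18]")
  expect_true(is_adverse_cytogenetics(cplx, 2017))
  expect_true(is_adverse_cytogenetics(cplx, 2022))

  # hyperdiploidy with multiple trisomies: adverse by complexity only in 2017
  hyper <- parse_karyotype("49,XX,+8,+13,+21[20]")
  expect_true(is_adverse_cytogenetics(hyper, 2017))
  expect_false(is_adverse_cytogenetics(hyper, 2022))

  # 2022 additions
  mecom <- parse_karyotype("46,XX,t(3;12)(q26.2;p13)[20]")
  expect_false(is_adverse_cytogenetics(mecom, 2017))
  expect_true(is_adverse_cytogenetics(mecom, 2022))
  kat6a <- parse_karyotype("46,XY,t(8;16)(p11.2;p13.3)[20]")
  expect_false(is_adverse_cytogenetics(kat6a, 2017))
  expect_true(is_adverse_cytogenetics(kat6a, 2022))

  expect_false(is_adverse_cytogenetics(parse_karyotype("46,XY[20]"), 2017))
  expect_false(is_adverse_cytogenetics(parse_karyotype("46,XY[20]"), 2022))
  expect_error(is_adverse_cytogenetics(cplx, 2010), "edition")
})

test_that("editions differ only via the documented cytogenetic mechanisms", {
  flags <- c("t_8_21", "inv16_or_t16_16", "t_9_11", "t_6_9", "t_v_11q23",
             "t_9_22", "t_8_16", "inv3_or_t3_3", "t_3q26_v",
             "del5q_or_minus5", "minus7", "minus17_or_abn17p",
             "complex", "monosomal", "hyperdiploid", "normal")
  make_features <- function(set) {
    f <- setNames(as.list(flags %in% set), flags)
    structure(c(f, list(abnormality_count = if (f$complex) 3L else length(set),
                        chromosome_count = if (f$hyperdiploid) 49L else 46L)),
              class = "karyotype_features")
  }
  combos <- unlist(lapply(0:4, function(k) combn(flags, k, simplify = FALSE)),
                   recursive = FALSE)
  for (set in combos) {
    if ("normal" %in% set && length(set) > 1) next
    f <- make_features(set)
    a17 <- is_adverse_cytogenetics(f, 2017)
    a22 <- is_adverse_cytogenetics(f, 2022)
    if (a17 != a22) {
      legit <- ("complex" %in% set && "hyperdiploid" %in% set) ||
        "t_3q26_v" %in% set || "t_8_16" %in% set
      expect_true(legit, info = paste(set, collapse = "+"))
    }
  }
})
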