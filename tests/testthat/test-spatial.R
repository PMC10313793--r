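test_that("gate rules parse and evaluate conjunction of disjunctions", {
  rule <- parse_gate_rule("t_il26 := (CD3D|CD3E|CD3G) & IL26")
  expect_equal(rule$name, "t_il26")
  expect_equal(rule$clauses, list(c("CD3D", "CD3E", "CD3G"), "IL26"))

  barcodes <- paste0("s", 1:4)
  calls <- calls_from_list(list(
    CD3D = c(FALSE, FALSE, TRUE, FALSE),
    CD3E = c(TRUE, FALSE, FALSE, FALSE),
    CD3G = c(FALSE, FALSE, FALSE, FALSE),
    IL26 = c(TRUE, TRUE, FALSE, FALSE),
    KRTDAP = c(FALSE, TRUE, TRUE, FALSE),
    TGFB1 = c(FALSE, TRUE, FALSE, FALSE),
    IFNG = c(FALSE, FALSE, FALSE, FALSE),
    IL17A = c(FALSE, FALSE, FALSE, FALSE)
  ), barcodes)
  # CD3E+IL26+ flagged; IL26+ without CD3 not; CD3D+ without IL26 not
  expect_equal(unname(gate_spots(calls, rule)),
               c(TRUE, FALSE, FALSE, FALSE))
  kc <- gate_rule("kc", list("KRTDAP", "TGFB1"))
  expect_equal(unname(gate_spots(calls, kc)),
               c(FALSE, TRUE, FALSE, FALSE))
  # all-negative spot never gated
  expect_false(any(vapply(default_gate_rules()[1:4], function(r) {
    gate_spots(calls, r)[["s4"]]
  }, logical(1))))
  expect_error(gate_spots(calls, gate_rule("bad", list("NOPE"))), "NOPE")
})

test_that("compartments and junction flags follow grid adjacency", {
  pos <- grid_positions(3, 4)
  keratin <- pos$array_row == 1
  calls <- calls_from_list(list(KRT5 = keratin, IL26 = rep(TRUE, 12)),
                           pos$barcode)
  epi_rule <- gate_rule("epi", list("KRT5"))
  sf <- assign_compartments(pos, calls, epi_rule, pitch = 100)
  expect_equal(as.character(sf$compartment[sf$barcode %in%
                                             pos$barcode[keratin]]),
               rep("epidermis", 4))
  # row 2 is adjacent to the epidermis, row 3 is not
  row_of <- pos$array_row[match(sf$barcode, pos$barcode)]
  expect_true(all(sf$junction[row_of <= 2]))
  expect_false(any(sf$junction[row_of == 3]))

  # 2-row grid: every spot touches the other compartment
  pos2 <- grid_positions(2, 3)
  calls2 <- calls_from_list(list(KRT5 = pos2$array_row == 1),
                            pos2$barcode)
  sf2 <- assign_compartments(pos2, calls2, epi_rule)
  expect_true(all(sf2$junction))

  # isolated epidermal spot beyond 1.2 x pitch: no junction anywhere
  pos3 <- grid_positions(1, 2, pitch = 100)
  pos3$array_col <- c(1, 10)
  pos3$pxl_col_in_fullres <- pos3$array_col * 100
  calls3 <- calls_from_list(list(KRT5 = c(TRUE, FALSE)), pos3$barcode)
  sf3 <- assign_compartments(pos3, calls3, epi_rule)
  expect_false(any(sf3$junction))

  calls4 <- calls_from_list(list(KRT5 = c(FALSE, FALSE)), pos3$barcode)
  expect_warning(assign_compartments(pos3, calls4, epi_rule),
                 "no epidermal")
})

test_that("minimum distances are exact Euclidean minima", {
  expect_equal(min_distance_to_class(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_equal(min_distance_to_class(rbind(c(2, 2)),
                                     rbind(c(9, 9), c(2, 2))), 0)
  expect_equal(
    min_distance_to_class(rbind(c(0, 0), c(10, 0)),
                          rbind(c(1, 0), c(8, 0))),
    c(1, 2)
  )
  expect_error(min_distance_to_class(rbind(c(0, 0)),
                                     matrix(numeric(0), 0, 2), "t_ifng"),
               "t_ifng")
})

test_that("minimum distances equal the exhaustive pairwise oracle exactly", {
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    m <- sample(1:60, 1)
    src <- matrix(runif(2 * n, 0, 5000), n, 2)
    tgt <- matrix(runif(2 * m, 0, 5000), m, 2)
    expect_identical(min_distance_to_class(src, tgt),
                     min_dist_oracle(src, tgt))
  }
})

test_that("KS statistic handles canonical cases", {
  ident <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$D, 0)
  expect_equal(ident$p, 1)
  disjoint <- ks_two_sample(c(0, 0, 0), c(1, 1, 1))
  expect_equal(disjoint$D, 1)
  mixed <- ks_two_sample(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  expect_equal(mixed$D, ks_D_oracle(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5)))
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS D matches the brute-force oracle and ks.test on random fixtures", {
  set.seed(31)
  for (rep in 1:50) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, 0, 1))
    ks <- ks_two_sample(a, b)
    expect_equal(ks$D, ks_D_oracle(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("KS D is invariant under strictly increasing transforms", {
  set.seed(32)
  for (rep in 1:10) {
    a <- rnorm(30)
    b <- rnorm(25, 0.3)
    expect_equal(ks_two_sample(a, b)$D, ks_two_sample(a^3, b^3)$D,
                 tolerance = 1e-12)
  }
})

test_that("asymptotic and permutation p-values agree on large samples", {
  set.seed(33)
  for (rep in 1:6) {
    a <- rnorm(150)
    b <- rnorm(150, mean = runif(1, 0, 0.35))
    ks <- ks_two_sample(a, b, n_perm = 2000, seed = rep)
    expect_lt(abs(ks$p - ks$p_perm), 0.02)
  }
})

test_that("contact counts split classes by epidermal contact", {
  pos <- grid_positions(4, 3)
  keratin <- pos$array_row == 1
  il26 <- pos$barcode %in% c("s02_01", "s03_02", "s04_03", "s01_01",
                             "s04_01")
  calls <- calls_from_list(list(KRT5 = keratin, IL26 = il26), pos$barcode)
  sf <- assign_compartments(pos, calls, gate_rule("epi", list("KRT5")))
  flags <- list(il26 = setNames(il26, pos$barcode))
  cc <- contact_counts(sf, flags)
  # s01_01 epidermal, s02_01 junction row -> in contact;
  # s03_02 and s04_* two+ rows away -> not in contact
  expect_equal(cc$in_contact, 2)
  expect_equal(cc$not_in_contact, 3)
})

test_that("junction co-expression reports exact fractions and undefined cases", {
  pos <- grid_positions(3, 4)
  keratin <- pos$array_row == 1
  row2 <- pos$array_row == 2
  il26 <- row2 # 4 junction IL26+ spots
  tgfb1 <- pos$barcode %in% c("s02_01", "s02_02", "s02_03")
  calls <- calls_from_list(list(KRT5 = keratin, IL26 = il26,
                                TGFB1 = tgfb1), pos$barcode)
  sf <- assign_compartments(pos, calls, gate_rule("epi", list("KRT5")))
  jc <- junction_coexpression(sf, setNames(il26, pos$barcode), calls,
                              "TGFB1")
  expect_equal(jc$percent, 75)
  expect_equal(jc$n_pos, 3L)
  expect_equal(jc$n_junction_primary, 4L)

  none <- setNames(rep(FALSE, nrow(pos)), pos$barcode)
  jc0 <- junction_coexpression(sf, none, calls, "TGFB1")
  expect_true(is.na(jc0$percent))
  expect_equal(jc0$n_junction_primary, 0L)
})
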