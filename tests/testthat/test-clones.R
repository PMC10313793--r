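make_stage <- function(stages, barcodes) {
  structure(list(
    stage = factor(setNames(stages, barcodes),
                   levels = c("early", "intermediate", "late")),
    t1 = 1, t2 = 2, mode = "absolute"
  ), class = "stage_assignment")
}

test_that("clone-stage table matches hand enumeration", {
  barcodes <- paste0("c", 1:6)
  clones <- data.frame(barcode = barcodes,
                       clonotype_id = c("A", "A", "B", "B", "C", "C"))
  stages <- make_stage(c("early", "late", "early", "early",
                         "intermediate", "late"), barcodes)
  calls <- calls_from_list(list(
    IL26 = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    IL17A = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)
  ), barcodes)
  t <- suppressMessages(clone_stage_table(clones, stages, calls))
  expect_equal(nrow(t), 5) # A:early+late, B:early, C:intermediate+late
  a_early <- t[t$clonotype_id == "A" & t$stage == "early", ]
  expect_equal(unlist(a_early[c("n_cells", "n_IL26_pos", "n_IL17A_pos")],
                      use.names = FALSE), c(1, 1, 0))
  a_late <- t[t$clonotype_id == "A" & t$stage == "late", ]
  expect_equal(unlist(a_late[c("n_cells", "n_IL26_pos", "n_IL17A_pos")],
                      use.names = FALSE), c(1, 0, 1))
  b_early <- t[t$clonotype_id == "B" & t$stage == "early", ]
  expect_equal(unlist(b_early[c("n_cells", "n_IL26_pos", "n_IL17A_pos")],
                      use.names = FALSE), c(2, 0, 0))

  # unmatched barcodes are dropped with a message, empty join errors
  clones2 <- rbind(clones, data.frame(barcode = "zz", clonotype_id = "D"))
  expect_message(clone_stage_table(clones2, stages, calls), "dropped")
  clones3 <- data.frame(barcode = "zz", clonotype_id = "D")
  expect_error(suppressMessages(clone_stage_table(clones3, stages, calls)),
               "no barcodes")
})

test_that("venn subsets assign each clone to exactly one subset", {
  barcodes <- paste0("c", 1:6)
  clones <- data.frame(barcode = barcodes,
                       clonotype_id = c("A", "A", "A", "B", "C", "C"))
  stages <- make_stage(c("early", "intermediate", "late", "early",
                         "intermediate", "late"), barcodes)
  calls <- calls_from_list(list(IL26 = rep(FALSE, 6),
                                IL17A = rep(FALSE, 6)), barcodes)
  t <- suppressMessages(clone_stage_table(clones, stages, calls))
  vc <- venn_counts(t)
  expect_equal(unname(vc["early&intermediate&late"]), 1L) # A
  expect_equal(unname(vc["early"]), 1L)                   # B
  expect_equal(unname(vc["intermediate&late"]), 1L)       # C
  expect_equal(sum(vc), 3L)
  expect_equal(attr(vc, "n_clones"), 3L)
})

test_that("venn counts partition random clone fixtures", {
  set.seed(20)
  for (rep in 1:5) {
    n_clones <- 50
    rows <- do.call(rbind, lapply(seq_len(n_clones), function(i) {
      stages <- sample(c("early", "intermediate", "late"),
                       sample(1:3, 1))
      data.frame(clonotype_id = sprintf("cl%02d", i), stage = stages,
                 n_cells = sample(1:4, length(stages), TRUE),
                 n_IL26_pos = 0L, n_IL17A_pos = 0L)
    }))
    rows$stage <- factor(rows$stage,
                         levels = c("early", "intermediate", "late"))
    class(rows) <- c("clone_stage_table", "data.frame")
    vc <- venn_counts(rows)
    expect_equal(sum(vc), n_clones)
    # higher presence threshold can only shrink membership
    vc3 <- venn_counts(rows, min_cells = 3)
    expect_lte(attr(vc3, "n_clones"), n_clones)
  }
})

test_that("late-producer provenance counts the X/Y/Z fixture", {
  # X late IL17A+ & early IL26+; Y late IL17A+ & early IL26-;
  # Z late IL17A+ but absent early
  t <- data.frame(
    clonotype_id = c("X", "X", "Y", "Y", "Z"),
    stage = c("early", "late", "early", "late", "late"),
    n_cells = c(2L, 1L, 1L, 2L, 1L),
    n_IL26_pos = c(1L, 0L, 0L, 0L, 0L),
    n_IL17A_pos = c(0L, 1L, 0L, 2L, 1L)
  )
  t$stage <- factor(t$stage, levels = c("early", "intermediate", "late"))
  prov <- late_producer_provenance(t)
  expect_equal(prov$n_late_IL17A_clones, 3)
  expect_equal(prov$n_with_early_presence, 2)
  expect_equal(prov$n_with_early_IL26pos, 1)
  expect_equal(prov$frac_early_IL26pos, 1 / 3)

  # no late IL17A+ clone: fractions undefined, not zero
  t0 <- t
  t0$n_IL17A_pos <- 0L
  prov0 <- late_producer_provenance(t0)
  expect_equal(prov0$n_late_IL17A_clones, 0)
  expect_true(is.na(prov0$frac_early_IL26pos))
})

test_that("sankey flows classify early/late shared clones only", {
  t <- data.frame(
    clonotype_id = c("X", "X", "Y", "Y", "Z"),
    stage = c("early", "late", "early", "late", "late"),
    n_cells = c(2L, 1L, 1L, 2L, 1L),
    n_IL26_pos = c(1L, 0L, 0L, 0L, 0L),
    n_IL17A_pos = c(0L, 1L, 0L, 2L, 1L)
  )
  t$stage <- factor(t$stage, levels = c("early", "intermediate", "late"))
  fl <- sankey_flows(t)
  get <- function(s, g) fl$n_clones[fl$source_state == s &
                                      fl$target_state == g]
  expect_equal(get("early_IL26+", "late_IL17A+"), 1L) # X
  expect_equal(get("early_IL26-", "late_IL17A+"), 1L) # Y
  expect_equal(sum(fl$n_clones), 2L)                  # Z excluded

  # empty early stage and single-stage clones give empty flows
  t_late <- t[t$stage == "late", ]
  expect_equal(sum(sankey_flows(t_late)$n_clones), 0L)
})
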