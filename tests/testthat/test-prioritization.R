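## Random but reproducible candidate tables for selection tests.
mk_candidates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    window_id = sprintf("w%03d", sample(ceiling(n / 2), n, replace = TRUE)),
    median_mt_ic50 = round(exp(runif(n, log(20), log(5000))), 2),
    fold_change = ifelse(runif(n) < 0.1, NA, round(exp(rnorm(n, 0, 1)), 3)),
    anchor_overlap = runif(n) < 0.3,
    tpm = ifelse(runif(n) < 0.15, 0, round(exp(rnorm(n, 2, 1)), 2)),
    rna_alt_reads = rpois(n, 2),
    proteome_match = runif(n) < 0.05,
    driver_flag = runif(n) < 0.2,
    clonality = sample(c("clonal", "subclonal"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("ensemble aggregation computes medians and fold change", {
  expect_equal(aggregate_ensemble(c(300, 450, 600))$median_mt_ic50, 450)
  agg <- aggregate_ensemble(c(100, 200), c(400, 800))
  expect_equal(agg$median_mt_ic50, 150)
  expect_equal(agg$median_wt_ic50, 600)
  expect_equal(agg$fold_change, 4)
  # frameshift: no WT partner, fold flagged undefined
  fs <- aggregate_ensemble(c(100, 200))
  expect_true(is.na(fs$fold_change) && is.na(fs$median_wt_ic50))
  expect_error(aggregate_ensemble(numeric(0)), "at least one")
  expect_error(aggregate_ensemble(c(1, 2), c(1, 2, 3)), "match")
  # median invariant to algorithm order
  expect_equal(aggregate_ensemble(c(600, 300, 450))$median_mt_ic50, 450)
})

test_that("anchor overlap uses position 2 and the C-terminus by default", {
  expect_true(anchor_overlap(2L, 9L))
  expect_false(anchor_overlap(5L, 9L))
  expect_true(anchor_overlap(11L, 11L))
  expect_true(anchor_overlap(9L, 9L))
  expect_false(anchor_overlap(NA_integer_, 9L))  # frameshift convention
  expect_equal(anchor_overlap(c(2, 3, 8), c(9, 9, 8)),
               c(TRUE, FALSE, TRUE))
  # per-allele override
  expect_true(anchor_overlap(5L, 9L, anchors = c(2L, 5L, NA)))
})

test_that("clonality rule compares against the patient maximum VAF", {
  expect_equal(classify_clonality(0.40, 0.45), "clonal")
  expect_equal(classify_clonality(0.10, 0.45), "subclonal")
  expect_equal(classify_clonality(0.45, 0.45, ratio = 1), "clonal")
  expect_equal(classify_clonality(c(0.4, 0.1), 0.45), c("clonal",
                                                        "subclonal"))
})

test_that("proteome screen equals a naive per-protein scan", {
  set.seed(31)
  proteome <- setNames(vapply(1:20, function(i)
    rand_protein(sample(40:90, 1)), character(1)), paste0("p", 1:20))
  # planted: an exact wild-type 9-mer is found
  planted <- substr(proteome[[3]], 11, 19)
  expect_true(screen_proteome(planted, proteome))
  peps <- c(planted, vapply(1:100, function(i) rand_protein(9),
                            character(1)))
  naive <- vapply(peps, function(p)
    any(vapply(proteome, function(pr) grepl(p, pr, fixed = TRUE),
               logical(1))), logical(1))
  expect_equal(screen_proteome(peps, proteome), unname(naive))
})

test_that("filters pass and fail with the documented reason codes", {
  base <- data.frame(median_mt_ic50 = 450, fold_change = 3,
                     anchor_overlap = FALSE, tpm = 5, rna_alt_reads = 2,
                     proteome_match = FALSE)
  expect_true(apply_filters(base)$passes)
  expect_equal(apply_filters(base)$reasons, "")
  anchored <- transform(base, anchor_overlap = TRUE, fold_change = 0.8)
  f <- apply_filters(anchored)
  expect_false(f$passes)
  expect_equal(f$reasons, "anchor_fold")
  # anchor overlap with favorable fold change still passes
  expect_true(apply_filters(transform(base, anchor_overlap = TRUE,
                                      fold_change = 1.5))$passes)
  weak <- apply_filters(transform(base, median_mt_ic50 = 600))
  expect_false(weak$passes)
  expect_equal(weak$reasons, "ic50")
  multi <- apply_filters(transform(base, median_mt_ic50 = 600, tpm = 0,
                                   proteome_match = TRUE))
  expect_equal(multi$reasons, "ic50,expression,proteome_match")
  # frameshift (NA fold) is exempt from the anchor clause
  fs <- apply_filters(transform(base, fold_change = NA))
  expect_true(fs$passes)
})

test_that("selection matches the brute-force comparator sort", {
  for (seed in c(1, 2, 3, 4, 5)) {
    cand <- mk_candidates(50, seed)
    got <- rank_and_select(cand, min_select = 1L)$selection
    want <- brute_select(cand)
    expect_equal(got$window_id, want$window_id)
    expect_equal(got$median_mt_ic50, want$median_mt_ic50)
  }
})

test_that("selection caps at max_select and is order-invariant", {
  set.seed(8)
  cand <- data.frame(window_id = sprintf("w%02d", 1:30),
                     median_mt_ic50 = runif(30, 50, 400),
                     fold_change = runif(30, 1.2, 5),
                     anchor_overlap = FALSE, tpm = 1, rna_alt_reads = 2,
                     proteome_match = FALSE, driver_flag = FALSE,
                     clonality = "clonal", stringsAsFactors = FALSE)
  sel <- rank_and_select(cand)
  expect_equal(sel$n_selected, 20L)
  perm <- cand[sample(nrow(cand)), ]
  expect_equal(rank_and_select(perm)$selection$window_id,
               sel$selection$window_id)
  # ranked by ascending IC50 given all else equal
  expect_equal(sel$selection$median_mt_ic50,
               sort(cand$median_mt_ic50)[1:20])
})

test_that("ties on every key break lexicographically by window id", {
  cand <- data.frame(window_id = c("wB", "wA"), median_mt_ic50 = 100,
                     fold_change = 2, anchor_overlap = FALSE, tpm = 1,
                     rna_alt_reads = 2, proteome_match = FALSE,
                     driver_flag = FALSE, clonality = "clonal",
                     stringsAsFactors = FALSE)
  sel <- rank_and_select(cand, min_select = 1L)
  expect_equal(sel$selection$window_id, c("wA", "wB"))
})

test_that("relaxation recovers additional windows and is recorded", {
  cand <- data.frame(window_id = sprintf("w%d", 1:5),
                     median_mt_ic50 = c(100, 200, 300, 700, 900),
                     fold_change = 2, anchor_overlap = FALSE, tpm = 1,
                     rna_alt_reads = 2, proteome_match = FALSE,
                     driver_flag = FALSE, clonality = "clonal",
                     stringsAsFactors = FALSE)
  sel <- rank_and_select(cand, min_select = 4L)
  expect_equal(sel$n_selected, 5L)  # 3 pass at 500; x2 relax recovers both
  expect_equal(sel$relax_level, 1L)
  # nothing passes even relaxed -> empty selection with warning
  hopeless <- transform(cand, tpm = 0)
  expect_warning(res <- rank_and_select(hopeless), "no candidate")
  expect_equal(res$n_selected, 0L)
  expect_equal(res$status, "empty")
})

test_that("raising the IC50 ceiling never drops a selected window", {
  cand <- mk_candidates(60, 17)
  th1 <- default_thresholds(ic50_max = 500)
  th2 <- default_thresholds(ic50_max = 1500)
  s1 <- rank_and_select(cand, min_select = 1L, max_select = 60L,
                        thresholds = th1)$selection$window_id
  s2 <- rank_and_select(cand, min_select = 1L, max_select = 60L,
                        thresholds = th2)$selection$window_id
  expect_true(all(s1 %in% s2))
})

test_that("driver and clonality preferences order the selection", {
  cand <- data.frame(window_id = c("w1", "w2", "w3"),
                     median_mt_ic50 = c(300, 200, 100),
                     fold_change = 2, anchor_overlap = FALSE, tpm = 1,
                     rna_alt_reads = 2, proteome_match = FALSE,
                     driver_flag = c(TRUE, FALSE, FALSE),
                     clonality = c("subclonal", "clonal", "subclonal"),
                     stringsAsFactors = FALSE)
  sel <- rank_and_select(cand, min_select = 1L)$selection
  expect_equal(sel$window_id, c("w1", "w2", "w3"))
})
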