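test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(missense_fraction = 1.2), "proportion")
  expect_error(cohort_config(n_patients = 0), "positive count")
  expect_error(cohort_config(protein_length_range = c(10, 40)), ">= 30")
  expect_error(cohort_config(protein_length_range = c(100, 50)),
               "increasing")
})

test_that("proteome generation is seeded, canonical and length-faithful", {
  cfg <- cohort_config(n_proteins = 40L, protein_length_range = c(30L, 30L),
                       seed = 7L)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1$proteins) == 30L))
  expect_false(anyDuplicated(names(p1$proteins)) > 0)
  expect_true(all(strsplit(paste(p1$proteins, collapse = ""), "")[[1]]
                  %in% AAS))
  expect_true(all(p1$expression$tpm >= 0))
  one <- generate_proteome(cohort_config(n_proteins = 1L,
                                         protein_length_range = c(30L, 30L),
                                         seed = 1L))
  expect_length(one$proteins, 1L)
  expect_equal(nchar(one$proteins[[1]]), 30L)
})

test_that("variant simulation honors type fraction, contracts and seed", {
  cfg <- cohort_config(missense_fraction = 1, seed = 3L)
  prot <- generate_proteome(cfg)
  v <- simulate_variants(prot, cfg)
  expect_true(all(v$type == "missense"))
  expect_identical(v, simulate_variants(prot, cfg))
  # positions always inside the protein; missense ref matches the protein
  lens <- nchar(prot$proteins[v$protein_id])
  expect_true(all(v$position >= 1L & v$position <= lens))
  expect_identical(v$ref, unname(substring(prot$proteins[v$protein_id],
                                           v$position, v$position)))
  expect_true(all(v$vaf > 0 & v$vaf <= 1))
  expect_true(all(v$rna_alt_reads >= 0))
})

test_that("variant counts and missense fraction recover config values", {
  cfg <- cohort_config(n_patients = 18L, n_proteins = 30L,
                       protein_length_range = c(60L, 100L),
                       mutations_per_patient_median = 21, seed = 11L)
  prot <- generate_proteome(cfg)
  meds <- numeric(200)
  n_mis <- n_tot <- 0
  for (i in 1:200) {
    v <- simulate_variants(prot, cfg, seed = 1000L + i)
    meds[i] <- median(table(v$patient_id))
    n_mis <- n_mis + sum(v$type == "missense")
    n_tot <- n_tot + nrow(v)
  }
  expect_lt(abs(median(meds) - 21), 2 + 1e-9)
  expect_lt(abs(n_mis / n_tot - cfg$missense_fraction), 0.02)
})

test_that("toy binding oracle is deterministic, bounded and motif-aware", {
  peps <- c("KLMNPQRST", "ACDEFGHK", "WYVTSRQPNM", "ACDEFGHIKLM")
  for (al in toy_alleles()) {
    ic <- toy_binding_oracle(peps, al)
    expect_identical(ic, toy_binding_oracle(peps, al))
    expect_true(all(ic > 0 & ic <= 50000))
    for (alg in toy_algorithms()) {
      expect_lt(toy_binding_oracle(allele_consensus(al), al, alg), 500)
      expect_gt(toy_binding_oracle(strrep("A", 9), al, alg), 5000)
    }
  }
  expect_error(toy_binding_oracle("ACDEFGXIK", "HLA-A*02:01"), "canonical")
  expect_error(toy_binding_oracle("ACDEFGH", "HLA-A*02:01"), "8-11")
  expect_error(toy_binding_oracle(strrep("A", 12), "HLA-A*02:01"), "8-11")
})

test_that("distinct ensemble algorithms perturb but do not reorder wildly", {
  p <- c("KLMNPQRST", "WYVTSRQPN")
  scores <- sapply(toy_algorithms(), function(a)
    toy_binding_oracle(p, "HLA-B*07:02", a))
  expect_true(all(apply(scores, 1, function(x) length(unique(x))) > 1))
})

test_that("whole-cohort simulation is byte-reproducible and consistent", {
  cfg <- small_config(seed = 7L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$elispot, c2$elispot)
  expect_identical(c1$clonotypes, c2$clonotypes)
  expect_identical(c1$followup, c2$followup)
  # truth consistency: each immunogenic epitope vaccinated in exactly one
  # patient's design
  truth <- c1$ground_truth$immunogenic_epitopes
  for (i in seq_len(nrow(truth))) {
    hits <- vapply(names(c1$designs), function(p)
      truth$neoantigen[i] %in% c1$designs[[p]]$selection$window_id,
      logical(1))
    expect_equal(sum(hits), 1L)
    expect_true(hits[[truth$patient[i]]])
  }
  # expanded clonotypes exist in the post-vaccination repertoire
  exp <- c1$ground_truth$expanded_clonotypes
  if (nrow(exp)) {
    post <- c1$clonotypes[c1$clonotypes$timepoint == "post", ]
    key <- paste(post$patient, post$neoantigen, post$cdr3b)
    expect_true(all(paste(exp$patient, exp$neoantigen, exp$cdr3b) %in% key))
  }
})

test_that("no-peptide background wells sit in the 10-120 SFC range", {
  co <- simulate_cohort(small_config(seed = 21L))
  bg <- co$elispot[co$elispot$stimulus == "none", ]
  means <- tapply(bg$count, paste(bg$patient, bg$timepoint), mean)
  # plate means are drawn inside [20, 100]; empirical means stay near them
  expect_true(all(means > 5 & means < 140))
})

test_that("assay simulation validates ground truth against designs", {
  co <- simulate_cohort(small_config(seed = 9L))
  bad <- data.frame(patient = "P01", neoantigen = "not_a_window")
  expect_error(simulate_assays(co$designs, bad, co$config),
               "not present in any vaccine design")
})

test_that("unit expansion factor produces a null clonotype contrast", {
  cfg <- small_config(seed = 13L, expansion_factor = 1)
  co <- simulate_cohort(cfg)
  cl <- co$clonotypes
  n_exp <- 0L
  for (k in unique(paste(cl$patient, cl$neoantigen, sep = "\r"))) {
    parts <- strsplit(k, "\r")[[1]]
    sub <- cl[cl$patient == parts[1] & cl$neoantigen == parts[2], ]
    ex <- test_expansion(
      build_clonotype_table(sub[sub$timepoint == "pre", ]),
      build_clonotype_table(sub[sub$timepoint == "post", ]))
    n_exp <- n_exp + sum(ex$expanded)
  }
  expect_equal(n_exp, 0L)
})

test_that("ICS readouts for truly immunogenic epitopes pass the rule", {
  co <- simulate_cohort(cohort_config(n_patients = 12L, n_proteins = 50L,
                                      protein_length_range = c(60L, 150L),
                                      mutations_per_patient_median = 12,
                                      n_clonotypes = 50L,
                                      clonotype_depth = 1000L, seed = 5L))
  truth <- co$ground_truth$immunogenic_epitopes
  expect_gt(nrow(truth), 10)
  pos <- vapply(seq_len(nrow(truth)), function(i) {
    r <- co$ics[co$ics$patient == truth$patient[i] &
                  co$ics$neoantigen == truth$neoantigen[i], ]
    any(ics_call(r$percent_pre, r$percent_post)$positive_strict)
  }, logical(1))
  expect_gt(mean(pos), 0.9)
})

test_that("follow-up respects the recurrence rate and arm structure", {
  cfg0 <- cohort_config(recurrence_rate = 0, seed = 2L)
  f0 <- simulate_followup(cfg0)
  expect_true(all(!f0$event[f0$arm == "vaccinated"]))
  expect_true(all(f0$time > 0))
  expect_identical(f0, simulate_followup(cfg0))
  cfg <- cohort_config(recurrence_rate = 2 / 18, seed = 2L)
  ev <- vapply(1:200, function(i) {
    f <- simulate_followup(cfg, seed = 5000L + i)
    sum(f$event[f$arm == "vaccinated"])
  }, numeric(1))
  expect_lt(abs(mean(ev) - 2), 0.5)
  # control arm carries a higher hazard than the vaccinated arm
  expect_gt(mean(f0$event[f0$arm == "control"]), 0.2)
})
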