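## Shared fixtures and independent oracles for the test suite. Oracles are
## deliberately naive re-derivations (enumeration, closed forms, pairwise
## comparison sorts) kept separate from the package implementation paths.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(len) paste(sample(AAS, len, replace = TRUE),
                                    collapse = "")

## Small, fast cohort configuration for end-to-end tests.
small_config <- function(seed = 7L, ...) {
  cohort_config(n_patients = 4L, n_proteins = 30L,
                protein_length_range = c(60L, 120L),
                mutations_per_patient_median = 8,
                n_clonotypes = 100L, clonotype_depth = 2000L,
                seed = seed, ...)
}

## Brute-force enumeration of minimal peptides overlapping the altered
## residues of a window (substring scan, no index arithmetic shared with
## the implementation).
brute_minimal_peptides <- function(window, lengths = 8:11) {
  n <- nchar(window$mt_sequence)
  m <- window$mut_offset + 1L
  altered <- if (window$variant_type == "missense") m else m:n
  res <- list()
  for (L in lengths) {
    if (n < L) next
    for (s in seq_len(n - L + 1L)) {
      if (any(altered >= s & altered <= s + L - 1L))
        res[[length(res) + 1L]] <- data.frame(
          start = s, length = L,
          mt = substr(window$mt_sequence, s, s + L - 1L),
          stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(start = integer(0), length = integer(0),
                  mt = character(0))
}

## Pairwise comparator for the selection rank key; TRUE iff a ranks
## strictly before b.
rank_before <- function(a, b) {
  keys <- list(
    function(x) -as.integer(x$passes),
    function(x) -as.integer(x$driver_flag),
    function(x) as.integer(x$clonality != "clonal"),
    function(x) x$median_mt_ic50,
    function(x) -(if (is.na(x$fold_change)) -Inf else x$fold_change),
    function(x) NA)  # sentinel: fall through to id comparison
  for (k in keys) {
    ka <- k(a); kb <- k(b)
    if (is.na(ka)) return(a$window_id < b$window_id)
    if (ka != kb) return(ka < kb)
  }
  FALSE
}

## Brute-force selection: best candidate per window and window ordering
## both found by exhaustive pairwise comparison.
brute_select <- function(candidates, thresholds = default_thresholds(),
                         max_select = 20L) {
  cand <- apply_filters(candidates, thresholds)
  reps <- list()
  for (w in unique(cand$window_id)) {
    rows <- which(cand$window_id == w)
    best <- rows[1L]
    for (r in rows[-1L])
      if (rank_before(cand[r, ], cand[best, ])) best <- r
    reps[[w]] <- cand[best, ]
  }
  reps <- reps[order(names(reps))]
  # selection sort by pairwise comparison
  ordered <- list()
  while (length(reps)) {
    besti <- 1L
    for (i in seq_along(reps))
      if (i != besti && rank_before(reps[[i]], reps[[besti]])) besti <- i
    ordered[[length(ordered) + 1L]] <- reps[[besti]]
    reps[[besti]] <- NULL
  }
  sel <- do.call(rbind, ordered)
  head(sel[sel$passes, , drop = FALSE], max_select)
}

## Hypergeometric tail by explicit enumeration with log-binomials.
hyper_tail_enum <- function(a, b, n_a, n_b) {
  K <- a + b
  N <- n_a + n_b
  xs <- seq.int(a, min(K, n_a))
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n_a - xs) - lchoose(N, n_a)))
}

## One-sided Welch t-test p-value from the closed form.
welch_p_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  pt(t, df, lower.tail = FALSE)
}

## Two-group log-rank chi-square from the textbook formula.
logrank_oracle <- function(arm_a, arm_b) {
  d <- rbind(data.frame(time = arm_a$time, event = as.integer(arm_a$event),
                        g = 1L),
             data.frame(time = arm_b$time, event = as.integer(arm_b$event),
                        g = 2L))
  ts <- sort(unique(d$time[d$event == 1L]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at <- d$time >= t
    n <- sum(at); n1 <- sum(at & d$g == 1L)
    dt <- sum(d$time == t & d$event == 1L)
    d1 <- sum(d$time == t & d$event == 1L & d$g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / n
    if (n > 1) V <- V + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1)
  }
  (O1 - E1)^2 / V
}
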