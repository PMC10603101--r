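# The fixed-delta fixture model has P-kmers shifted +0.2 from their
# G-substituted counterparts, sigma 0.4 (see helper-fixtures.R).

levels_at_model <- function(model, seq, n_pad = 3) {
  starts <- seq_len(nchar(seq) - 4 + 1)
  mus <- xenocall:::model_mu(model, substring(seq, starts, starts + 3))
  c(mus, rep(0, n_pad))
}

test_that("sequence likelihood peaks at the emitting sequence", {
  m <- fixed_delta_model()
  hep <- "AGTPCGT"
  lv <- levels_at_model(m, hep)
  starts <- decompose_heptamer(hep, 4)$start
  ll_p <- sequence_log10_likelihood(lv, hep, m, starts)
  peak <- log10(1 / (0.4 * sqrt(2 * pi)))
  expect_equal(ll_p, 4 * peak)
  ll_g <- sequence_log10_likelihood(lv, "AGTGCGT", m, starts)
  expect_lt(ll_g, ll_p)
})

test_that("sequence likelihood is translation invariant and matches the product oracle", {
  m <- fixed_delta_model()
  hep <- "AGTPCGT"
  starts <- 1:4
  set.seed(17)
  lv <- rnorm(7)
  ll <- sequence_log10_likelihood(lv, hep, m, starts)
  # independent oracle: product of per-kmer densities, taken in log space
  kmers <- substring(hep, starts, starts + 3)
  dens <- dnorm(lv[starts],
                mean = xenocall:::model_mu(m, kmers), sd = 0.4)
  expect_equal(ll, log10(prod(dens)), tolerance = 1e-12)
  # adding a constant to every mu and every level leaves the value unchanged
  m2 <- m
  m2$entries$mu <- m2$entries$mu + 1.7
  expect_equal(sequence_log10_likelihood(lv + c(rep(1.7, 4), 0, 0, 0),
                                         hep, m2, starts),
               ll, tolerance = 1e-10)
  # missing kmer -> coverage error naming it
  expect_error(sequence_log10_likelihood(lv, "TTTTCGT", m, starts),
               "TTTT")
})

test_that("LLR is antisymmetric, favors the emitting base, and matches the single-kmer closed form", {
  m <- fixed_delta_model()
  hep <- "AGTPCGT"
  set.seed(23)
  for (i in 1:10) {
    lv <- rnorm(7)
    expect_equal(llr(lv, hep, 4, "P", "G", m),
                 -llr(lv, hep, 4, "G", "P", m), tolerance = 1e-12)
  }
  lv_p <- levels_at_model(m, hep)
  expect_gt(llr(lv_p, hep, 4, "P", "G", m), 0)
  # single-kmer closed form: ((I-mu_j)^2 - (I-mu_i)^2) * log10(e) / (2 sigma^2)
  h <- xenocall:::hypothesis_kmers(hep, 4, "P", "G", m)
  lv <- rnorm(7)
  terms <- xenocall:::llr_terms(lv, hep, 4, "P", "G", m)
  for (j in 1:4) {
    x <- lv[h$starts[j]]
    closed <- ((x - h$mu_j[j])^2 - (x - h$mu_i[j])^2) *
      log10(exp(1)) / (2 * 0.4^2)
    expect_equal(terms[j], closed, tolerance = 1e-12)
  }
})

test_that("ORLLR per-kmer terms keep the LLR sign and vanish at the midpoint", {
  m <- fixed_delta_model()
  hep <- "AGTPCGT"
  h <- xenocall:::hypothesis_kmers(hep, 4, "P", "G", m)
  set.seed(29)
  for (i in 1:25) {
    lv <- rnorm(7, sd = 2)
    x <- lv[h$starts]
    lt <- xenocall:::llr_terms(lv, hep, 4, "P", "G", m)
    ot <- xenocall:::orllr_transform(lt, x, h$mu_i, h$mu_j, h$sigma,
                                     orllr_params())
    expect_equal(sign(ot), sign(lt))
  }
  # observed level at the two-model midpoint gives a zero term
  mid <- (h$mu_i[1] + h$mu_j[1]) / 2
  lv <- rep(0, 7); lv[h$starts[1]] <- mid
  lt <- xenocall:::llr_terms(lv, hep, 4, "P", "G", m)
  ot <- xenocall:::orllr_transform(lt, lv[h$starts], h$mu_i, h$mu_j,
                                   h$sigma, orllr_params())
  expect_equal(ot[1], 0)
  # degenerate mu_i == mu_j contributes 0, not an error
  expect_equal(xenocall:::orllr_transform(1.5, 0.3, 0.7, 0.7, 0.4,
                                          orllr_params()), 0)
})

test_that("ORLLR matches an independent step-by-step evaluation", {
  # literal transcription of the printed formula, evaluated piecewise
  orllr_by_hand <- function(llr_value, level, mu_i, mu_j, sigma,
                            sf = 4, sf2 = 3, sp = 0.3) {
    sc_diff <- level - (mu_i + mu_j) / 2
    mu_sep <- abs(mu_i - mu_j)
    damp <- exp(-(sc_diff^2 / (sf * sigma^2)))
    damp * llr_value / (sigma^2 * mu_sep^sp * sf2)
  }
  # the worked single-kmer case: sigma 0.4, mu_i 0.5, mu_j 0.9, I 0.5
  llr_1 <- (((0.5 - 0.9)^2 - (0.5 - 0.5)^2) * log10(exp(1))) / (2 * 0.4^2)
  expect_equal(
    xenocall:::orllr_transform(llr_1, 0.5, 0.5, 0.9, 0.4, orllr_params()),
    orllr_by_hand(llr_1, 0.5, 0.5, 0.9, 0.4),
    tolerance = 1e-12
  )
  set.seed(31)
  for (i in 1:100) {
    mu_i <- rnorm(1); mu_j <- rnorm(1); x <- rnorm(1); s <- runif(1, 0.1, 1)
    lt <- xenocall::level_log10_pdf(x, mu_i, s) -
      xenocall::level_log10_pdf(x, mu_j, s)
    expect_equal(
      xenocall:::orllr_transform(lt, x, mu_i, mu_j, s, orllr_params()),
      orllr_by_hand(lt, x, mu_i, mu_j, s),
      tolerance = 1e-12
    )
  }
})

test_that("position calls pick the emitting base and respect the threshold", {
  m <- fixed_delta_model()
  hep <- "AGTPCGT"
  # levels exactly at the null (XNA) means: null retained
  lv_null <- tibble::as_tibble(tiny_level_table()[1, ])
  lv_null$levels <- list(levels_at_model(m, hep))
  lv_null$reference_seq <- hep
  calls <- call_positions(xenocall:::as_xna_levels(lv_null), m,
                          statistic = "llr", candidates = "G")
  expect_equal(calls$called_base, "P")
  expect_lt(calls$best_stat, 0)
  # levels at the candidate's means: candidate called
  lv_g <- lv_null
  lv_g$levels <- list(levels_at_model(m, "AGTGCGT"))
  calls_g <- call_positions(xenocall:::as_xna_levels(lv_g), m,
                            statistic = "llr", candidates = "G")
  expect_equal(calls_g$called_base, "G")
  # a prohibitive threshold forces the null
  calls_thr <- call_positions(xenocall:::as_xna_levels(lv_g), m,
                              statistic = "llr", candidates = "G",
                              threshold = 1e6)
  expect_equal(calls_thr$called_base, "P")
})

test_that("two-candidate LLR decision equals the total-likelihood argmax", {
  m <- fixed_delta_model()
  lv <- simulate_reads(m, c(h = "AGTPCGT"), n_per_seq = 200, seed = 41)
  calls <- call_positions(lv, m, statistic = "llr", candidates = "G")
  starts <- decompose_heptamer("AGTPCGT", 4)$start
  byml <- vapply(lv$levels, function(v) {
    lp <- sequence_log10_likelihood(v, "AGTPCGT", m, starts)
    lg <- sequence_log10_likelihood(v, "AGTGCGT", m, starts)
    if (lg > lp) "G" else "P"
  }, character(1))
  expect_equal(calls$called_base, byml)
  # reported likelihoods agree with direct evaluation
  expect_equal(calls$scores[[1]]$loglik,
               sequence_log10_likelihood(lv$levels[[1]], "AGTGCGT", m, starts))
})

test_that("calls are invariant under read reordering and ties break alphabetically", {
  m <- synthetic_model(4, c("P", "Z"), seed = 43)
  lv <- simulate_reads(m, c(h = "ACGPTTA"), n_per_seq = 50, seed = 44)
  c1 <- call_positions(lv, m, statistic = "orllr", candidates = "standard")
  c2 <- call_positions(lv[rev(seq_len(nrow(lv))), ], m,
                       statistic = "orllr", candidates = "standard")
  expect_equal(dplyr::arrange(c1, read_id)$called_base,
               dplyr::arrange(c2, read_id)$called_base)
  # candidate ordering is the deterministic collation
  expect_equal(c1$scores[[1]]$candidate, c("A", "C", "G", "T"))
})

test_that("consensus calling takes the majority with no-calls below min_reads", {
  calls <- tibble::tibble(
    read_id = paste0("r", 1:10),
    reference_name = "ref",
    position = 4L,
    null_base = "P",
    called_base = rep("P", 10)
  )
  cc <- consensus_call(calls, min_reads = 10)
  expect_equal(cc$called_base, "P")
  expect_equal(cc$n_reads, 10)
  # 6 vs 4 majority
  calls2 <- dplyr::mutate(calls, called_base = rep(c("P", "G"), c(6, 4)))
  expect_equal(consensus_call(calls2, min_reads = 10)$called_base, "P")
  # below min_reads: no-call
  cc3 <- consensus_call(calls[1:5, ], min_reads = 10)
  expect_true(is.na(cc3$called_base))
  expect_equal(cc3$no_call_reason, "min_reads")
  # exact tie: no-call
  calls4 <- dplyr::mutate(calls, called_base = rep(c("P", "G"), 5))
  cc4 <- consensus_call(calls4, min_reads = 10)
  expect_true(is.na(cc4$called_base))
  expect_equal(cc4$no_call_reason, "tie")
})

test_that("majority-vote recall follows the exact binomial for odd read counts", {
  # analytic property: per-read recall r > 0.5 implies consensus recall
  # >= r at odd n, via exact binomial tail sums
  maj <- function(r, n) sum(dbinom(ceiling((n + 1) / 2):n, n, r))
  for (r in c(0.55, 0.7, 0.9)) {
    for (n in c(11, 21, 51)) {
      expect_gte(maj(r, n), r)
    }
  }
  # and the simulated pipeline reproduces the binomial value (n = 11 reads)
  m <- fixed_delta_model(delta = 0.15)
  r <- theoretical_recall(m, "AGTPCGT", "P", "G")
  expect_gt(r, 0.5)
  n_groups <- 200
  seqs <- stats::setNames(rep("AGTPCGT", n_groups), paste0("g", seq_len(n_groups)))
  lv <- simulate_reads(m, seqs, n_per_seq = 11, seed = 45)
  calls <- call_positions(lv, m, statistic = "llr", candidates = "G")
  cc <- consensus_call(calls, min_reads = 11)
  cons_recall <- mean(cc$called_base == "P", na.rm = TRUE)
  expected <- maj(r, 11)
  expect_lt(abs(cons_recall - expected),
            3 * sqrt(expected * (1 - expected) / n_groups))
})
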