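test_that("heptamer decomposition yields the four covering kmers", {
  d <- decompose_heptamer("AGTBCCT", 4)
  expect_equal(d$kmer, c("AGTB", "GTBC", "TBCC", "BCCT"))
  expect_equal(d$offset, c(2L, 1L, 0L, -1L))
  expect_equal(d$start, 1:4)
  expect_equal(decompose_heptamer("AAAAAAA", 4)$kmer, rep("AAAA", 4))
  # every returned kmer contains the focal letter
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(9)
    pos <- sample(4:6, 1)
    kk <- decompose_heptamer(s, pos)$kmer
    focal <- substr(s, pos, pos)
    expect_true(all(grepl(focal, kk, fixed = TRUE)))
    expect_length(kk, 4)
  }
  expect_error(decompose_heptamer("AGTBCCT", 2), "context")
  expect_error(decompose_heptamer("AGTBCCT", 6), "context")
})

test_that("all location estimators recover a Gaussian mean", {
  set.seed(101)
  n <- 10000
  mu_true <- 0.7
  sigma_true <- 0.4
  obs <- tibble::tibble(kmer = "AGTB", level = rnorm(n, mu_true, sigma_true))
  tol <- 3 * sigma_true / sqrt(n)
  for (est in c("mean", "median", "kde", "kde_mean")) {
    m <- fit_kmer_model(obs, estimator = est)
    expect_lt(abs(m$entries$mu - mu_true),
              if (est == "median") 1.3 * 3 * 1.253 * sigma_true / sqrt(n)
              else if (est == "kde") 0.02 else tol)
    # estimator choice never alters the raw summaries
    expect_equal(m$entries$coverage, n)
    expect_equal(m$entries$median, stats::median(obs$level))
    expect_equal(m$entries$min, min(obs$level))
    expect_equal(m$entries$max, max(obs$level))
  }
})

test_that("fit handles single observations and rejects empty input", {
  m <- fit_kmer_model(tibble::tibble(kmer = "ACGT", level = 0.37))
  expect_equal(m$entries$mu, 0.37)
  expect_equal(m$entries$std, 0)
  expect_equal(m$entries$coverage, 1L)
  expect_error(fit_kmer_model(tibble::tibble(kmer = character(),
                                             level = numeric())),
               "no level observations")
})

test_that("global sigma is the mean of per-kmer standard deviations", {
  set.seed(5)
  obs <- tibble::tibble(
    kmer = rep(c("AAAA", "ACGT", "TTTT"), each = 50),
    level = c(rnorm(50, 0, 0.2), rnorm(50, 1, 0.5), rnorm(50, -1, 0.8))
  )
  m <- fit_kmer_model(obs)
  expect_equal(m$global_sigma, mean(m$entries$std))
})

test_that("KDE bandwidth follows the Silverman-style rule", {
  set.seed(9)
  x <- rnorm(500, 0, 0.4)
  n <- length(x)
  a_expected <- 0.9 * min(stats::IQR(x) / 1.34, stats::sd(x))
  expect_equal(kde_bandwidth(x), a_expected * n^(-1 / 5))
  # whichever of IQR/1.34 and sd is smaller drives A
  y <- c(rnorm(50, 0, 0.1), rnorm(5, 0, 10))   # heavy tails: IQR/1.34 < sd
  stopifnot(stats::IQR(y) / 1.34 < stats::sd(y))
  expect_equal(kde_bandwidth(y),
               0.9 * (stats::IQR(y) / 1.34) * length(y)^(-1 / 5))
  expect_warning(bw0 <- kde_bandwidth(rep(1, 10)), "constant")
  expect_gt(bw0, 0)
})

test_that("KDE mode recovers the mean of a large Gaussian sample", {
  set.seed(11)
  x <- rnorm(10000, 0.7, 0.4)
  expect_lt(abs(xenocall:::kde_mode(x) - 0.7), 0.02)
  expect_lt(abs(xenocall:::kde_mean(x) - mean(x)), 0.01)
})

test_that("level density is a correctly normalized log10 Gaussian", {
  sigma <- 0.4
  peak <- level_log10_pdf(0.7, 0.7, sigma)
  expect_equal(peak, log10(1 / (sigma * sqrt(2 * pi))))
  # symmetric about mu
  expect_equal(level_log10_pdf(0.7 + 0.13, 0.7, sigma),
               level_log10_pdf(0.7 - 0.13, 0.7, sigma))
  # one sigma from the mean: density of N(0, 0.4) at 0.4 is 0.6049
  expect_equal(10^level_log10_pdf(0.4, 0, 0.4),
               exp(-0.5) / (0.4 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(round(10^level_log10_pdf(0.4, 0, 0.4), 3), 0.605)
  # integrates to one for representative parameters
  for (p in list(c(0, 0.4), c(0.7, 0.1), c(-2, 1.3))) {
    total <- stats::integrate(function(x) 10^level_log10_pdf(x, p[1], p[2]),
                              -Inf, Inf)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(level_log10_pdf(0, 0, 0), "positive")
})

test_that("model fitting on simulated reads recovers the generating model", {
  m <- synthetic_model(4, "P", seed = 31)
  n <- 1000
  heps <- c(h1 = "AGTPCGT", h2 = "CCAPTTG", h3 = "TGCPAAC")
  lv <- simulate_reads(m, heps, n_per_seq = n, seed = 32)
  obs <- purrr::map_dfr(seq_len(nrow(lv)), function(i) {
    s <- lv$reference_seq[i]
    tibble::tibble(kmer = substring(s, 1:4, 4:7),
                   level = lv$levels[[i]][1:4])
  })
  fit <- fit_kmer_model(obs, estimator = "mean")
  truth <- m$entries$mu[match(fit$entries$kmer, m$entries$kmer)]
  expect_true(all(abs(fit$entries$mu - truth) < 4 * 0.4 / sqrt(n)))
})

test_that("model files round-trip and reject malformed input", {
  set.seed(13)
  obs <- tibble::tibble(kmer = rep(c("AGTP", "GTPC"), each = 30),
                        level = rnorm(60))
  m <- fit_kmer_model(obs, estimator = "median", sigma_policy = "global")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_kmer_model(m, tf)
  back <- read_kmer_model(tf)
  expect_equal(back$entries, m$entries)
  expect_equal(back$k, m$k)
  expect_equal(back$global_sigma, m$global_sigma)
  expect_equal(back$sigma_policy, m$sigma_policy)
  expect_equal(back$estimator, m$estimator)

  # duplicate kmer rows rejected
  lines <- readr::read_lines(tf)
  dup <- c(lines, lines[length(lines)])
  tf2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(dup, tf2)
  expect_error(read_kmer_model(tf2), "duplicate kmer")

  # missing mu column rejected
  entries <- m$entries
  tf3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(entries, -"mu"), tf3)
  expect_error(read_kmer_model(tf3), "mu")

  # a single-pair model at k = 4 has at most 512 XNA kmer rows
  full <- synthetic_model(4, c("P", "Z"), seed = 1)
  expect_equal(sum(grepl("[^ACGT]", full$entries$kmer)), 512)
})

test_that("tidy and glance summarize kmer models", {
  m <- synthetic_model(4, "P", seed = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 512)
  expect_equal(sum(td$n_xna), 256)
  gl <- glance(m)
  expect_equal(gl$n_kmers, 512)
  expect_equal(gl$n_xna_kmers, 256)
  expect_equal(gl$global_sigma, 0.4)
})
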