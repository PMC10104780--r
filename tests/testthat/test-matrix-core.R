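test_that("ICE balancing: fixed point, factorizable bias recovery, degenerate bin", {
  # doubly-stochastic input: uniform off-diagonal matrix is already balanced
  bins <- bin_table(c(chr1 = 8e5), 1e5)
  ij <- which(upper.tri(matrix(0, 8, 8), diag = TRUE), arr.ind = TRUE)
  m <- contact_matrix(bins, data.frame(bin1_id = ij[, 1], bin2_id = ij[, 2],
                                       count = 5))
  mb <- ice_balance(m, ignore_diags = 0, mad_max = Inf)
  w <- mb$weights
  expect_true(all(abs(w / w[1] - 1) < 1e-4))

  # counts c_ij = r_i r_j (exactly factorizable): balanced matrix must
  # match the Sinkhorn oracle and weights must be proportional to 1/r
  r <- c(1, 2, 3, 4, 5)
  C <- outer(r, r) * 10
  bins5 <- bin_table(c(chr1 = 5e5), 1e5)
  ij <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  m5 <- contact_matrix(bins5, data.frame(bin1_id = ij[, 1],
                                         bin2_id = ij[, 2],
                                         count = C[cbind(ij[, 1], ij[, 2])]))
  mb5 <- ice_balance(m5, ignore_diags = 0, mad_max = Inf, tol = 1e-10)
  b_oracle <- sinkhorn_oracle(dense_counts(m5), rep(TRUE, 5), 0)
  B_pkg <- dense_counts(m5) * outer(mb5$weights, mb5$weights)
  B_orc <- dense_counts(m5) * outer(b_oracle, b_oracle)
  expect_lt(max(abs(B_pkg - B_orc)), 1e-6)
  # weights proportional to 1/r
  expect_lt(diff(range(mb5$weights * r)) / mean(mb5$weights * r), 1e-4)

  # an all-zero bin is filtered to NA and the rest still converge
  C2 <- C; C2[3, ] <- 0; C2[, 3] <- 0
  ij2 <- which(upper.tri(C2, diag = TRUE) & C2 > 0, arr.ind = TRUE)
  m0 <- contact_matrix(bins5, data.frame(bin1_id = ij2[, 1],
                                         bin2_id = ij2[, 2],
                                         count = C2[ij2]))
  mb0 <- ice_balance(m0, ignore_diags = 0, mad_max = Inf)
  expect_true(is.na(mb0$weights[3]))
  expect_true(all(!is.na(mb0$weights[-3])))
})

test_that("balanced marginals are equal within tolerance on a simulated map", {
  cfg <- hic_sim_config(chrom_sizes = c(chr1 = 1e7, chr2 = 8e6),
                        bin_size = 1e5, n_pairs = 5e5, seed = 13)
  m <- ice_balance(simulate_contact_map(cfg, "control"), tol = 1e-6)
  # recompute marginals with the first two diagonals masked
  for (ch in c("chr1", "chr2")) {
    B <- dense_chrom_test(m, ch)
    good <- !is.na(B[, 1]) | colSums(!is.na(B)) > 0
    D <- abs(row(B) - col(B))
    B[D < 2] <- 0
    marg <- rowSums(B, na.rm = TRUE)
    ok <- is.finite(marg) & marg > 0
    expect_lt(max(abs(marg[ok] / mean(marg[ok]) - 1)), 1e-5)
  }
})

test_that("expected_cis matches the dense averaging oracle and flags empty diagonals", {
  bins <- bin_table(c(chr1 = 4e5), 1e5)
  C <- matrix(c(4, 2, 1, 0,
                2, 6, 3, 1,
                1, 3, 5, 2,
                0, 1, 2, 7), 4, 4, byrow = TRUE)
  ij <- which(upper.tri(C, diag = TRUE) & C > 0, arr.ind = TRUE)
  m <- contact_matrix(bins, data.frame(bin1_id = ij[, 1], bin2_id = ij[, 2],
                                       count = C[ij]))
  m$weights <- rep(1, 4)
  ex <- expected_cis(m)
  oracle <- diag_means_oracle(C, rep(TRUE, 4))
  expect_equal(ex$expected, oracle)

  # constant-diagonal balanced matrix returns those constants
  Cc <- matrix(0, 4, 4)
  for (d in 0:3) Cc[row(Cc) - col(Cc) == -d | col(Cc) - row(Cc) == -d] <- 10 - d
  ijc <- which(upper.tri(Cc, diag = TRUE), arr.ind = TRUE)
  mc <- contact_matrix(bins, data.frame(bin1_id = ijc[, 1],
                                        bin2_id = ijc[, 2], count = Cc[ijc]))
  mc$weights <- rep(1, 4)
  expect_equal(expected_cis(mc)$expected, c(10, 9, 8, 7))

  # a fully filtered diagonal is undefined, not zero
  m$weights <- c(1, NA, 1, NA)
  ex2 <- expected_cis(m)
  expect_true(is.na(ex2$expected[ex2$diag == 3]))  # pair (1,4) has NA weight
  expect_error(expected_cis(contact_matrix(bins, data.frame(
    bin1_id = 1, bin2_id = 2, count = 3))), "not balanced")
})

test_that("O/E normalizes every diagonal mean to 1 and matches a dense oracle", {
  cfg <- hic_sim_config(chrom_sizes = c(chr1 = 5e6), bin_size = 1e5,
                        kappa = 0.3, block_bins = 5, n_pairs = 4e5,
                        seed = 17)
  m <- ice_balance(simulate_contact_map(cfg, "control"))
  oe <- observed_over_expected(m)
  M <- oe$chroms$chr1
  n <- nrow(M)
  for (d in 0:(n - 1)) {
    vals <- M[col(M) - row(M) == d]
    vals <- vals[is.finite(vals)]
    if (length(vals) > 0) expect_lt(abs(mean(vals) - 1), 1e-9)
  }

  # 4x4 worked case against elementwise division by the diagonal means
  bins <- bin_table(c(chr1 = 4e5), 1e5)
  C <- matrix(c(8, 4, 2, 1,
                4, 6, 5, 2,
                2, 5, 9, 3,
                1, 2, 3, 7), 4, 4, byrow = TRUE)
  ij <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  m4 <- contact_matrix(bins, data.frame(bin1_id = ij[, 1], bin2_id = ij[, 2],
                                        count = C[ij]))
  m4$weights <- rep(1, 4)
  oe4 <- observed_over_expected(m4)$chroms$chr1
  ev <- diag_means_oracle(C, rep(TRUE, 4))
  O <- C / ev[abs(row(C) - col(C)) + 1]
  expect_equal(oe4, O)
})

test_that("P(s) derivative recovers planted exponents and ignores count scale", {
  # deterministic power law: derivative is the exponent analytically
  m <- powerlaw_matrix(n_bins = 400, alpha = 1, K = 1e5)
  sc <- contact_scaling(m)
  mid <- sc$deriv[sc$s > 2e5 & sc$s < 5e6]
  expect_true(all(abs(mid - (-1)) < 0.05))

  # uniform count rescaling leaves the derivative unchanged
  m2 <- powerlaw_matrix(n_bins = 400, alpha = 1, K = 3e5)
  sc2 <- contact_scaling(m2)
  expect_equal(sc2$deriv, sc$deriv, tolerance = 1e-2)

  expect_error(contact_scaling(powerlaw_matrix(n_bins = 3), 8, 1e10),
               "min_separation")
})

test_that("insulation is flat on uniform maps and dips at planted boundaries", {
  # uniform balanced map -> insulation identically 0 where defined
  n <- 40
  bins <- bin_table(c(chr1 = n * 1e5), 1e5)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  m <- contact_matrix(bins, data.frame(bin1_id = ij[, 1], bin2_id = ij[, 2],
                                       count = 10))
  m$weights <- rep(1, n)
  ins <- insulation_profile(m, window = 5e5)
  w <- 5L
  expect_true(all(is.na(ins$values[c(1:w, (n - w + 1):n)])))
  defined <- ins$values[!is.na(ins$values)]
  expect_true(all(abs(defined) < 1e-12))

  # block-diagonal map: boundary bin scores the genome-wide minimum
  C <- matrix(1, n, n); C[1:20, 21:40] <- 0; C[21:40, 1:20] <- 0
  ij <- which(upper.tri(C, diag = TRUE) & C > 0, arr.ind = TRUE)
  mb <- contact_matrix(bins, data.frame(bin1_id = ij[, 1], bin2_id = ij[, 2],
                                        count = 10))
  mb$weights <- rep(1, n)
  insb <- insulation_profile(mb, window = 5e5)
  # diamond-mean oracle at the boundary and at a mid-block bin
  B <- dense_counts(mb)
  diamond <- function(i) mean(B[(i - w):(i - 1), (i + 1):(i + w)])
  raw <- vapply((w + 1):(n - w), diamond, 0)
  expect_equal(which.min(insb$values[(w + 1):(n - w)]), which.min(raw))
  expect_equal(which.min(raw) + w, 20)  # the planted boundary between 20|21

  expect_error(insulation_profile(m, window = 1e5), "at least 2 bins")
})

test_that("downsampling hits the target exactly and is mean-unbiased", {
  bins <- bin_table(c(chr1 = 2e6), 1e5)
  set.seed(23)
  ij <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  sel <- sample(nrow(ij), 25)
  px <- data.frame(bin1_id = ij[sel, 1], bin2_id = ij[sel, 2],
                   count = rpois(25, 40) + 1)
  m <- contact_matrix(bins, px)
  expect_identical(downsample(m, m$total_valid_pairs), m)
  expect_equal(downsample(m, 0)$total_valid_pairs, 0)
  expect_error(downsample(m, m$total_valid_pairs + 1), "exceeds")

  target <- round(m$total_valid_pairs / 3)
  d1 <- downsample(m, target, seed = 1)
  expect_equal(d1$total_valid_pairs, target)
  expect_identical(downsample(m, target, seed = 1)$pixels, d1$pixels)

  # expected thinned count = count * target/total, within 3 SE over 200 seeds
  probe <- paste(px$bin1_id[1], px$bin2_id[1])
  draws <- vapply(1:200, function(s) {
    d <- downsample(m, target, seed = s)
    key <- paste(d$pixels$bin1_id, d$pixels$bin2_id)
    hit <- d$pixels$count[key == probe]
    if (length(hit) == 0) 0 else hit
  }, 0)
  p <- target / m$total_valid_pairs
  mu <- px$count[1] * p
  se <- sqrt(px$count[1] * p * (1 - p)) / sqrt(200)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("pooling sums pixels and reproduces the pooled-depth arithmetic", {
  bins <- bin_table(c(chr1 = 3e5), 1e5)
  m <- contact_matrix(bins, data.frame(bin1_id = c(1, 2), bin2_id = c(2, 3),
                                       count = c(3, 4)))
  mm <- pool(list(m, m))
  expect_equal(mm$pixels$count, c(6, 8))
  expect_identical(pool(list(m))$pixels, m$pixels)

  # two replicates downsampled to equal depth pool to exactly twice it
  big <- contact_matrix(bins, data.frame(bin1_id = c(1, 1, 2),
                                         bin2_id = c(2, 3, 3),
                                         count = c(3e7, 2e7, 2e7)))
  r1 <- downsample(big, 56446063, seed = 1)
  r2 <- downsample(big, 56446063, seed = 2)
  expect_equal(pool(list(r1, r2))$total_valid_pairs, 112892126)

  bins2 <- bin_table(c(chr1 = 4e5), 1e5)
  m2 <- contact_matrix(bins2, data.frame(bin1_id = 1, bin2_id = 2, count = 1))
  expect_error(pool(list(m, m2)), "bin tables differ")
})
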