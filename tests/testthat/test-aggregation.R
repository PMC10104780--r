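test_that("cis pair enumeration matches per-chromosome C(n,2) brute force", {
  s3 <- site_catalog(rep("chr1", 3), c(1e6, 2e6, 3e6), name = c("a", "b", "c"))
  expect_equal(nrow(cis_pairs(s3)), 3)
  strans <- site_catalog(paste0("chr", 1:4), rep(5e5, 4))
  expect_equal(nrow(cis_pairs(strans)), 0)

  set.seed(9)
  cat_r <- site_catalog(sample(paste0("chr", 1:5), 40, replace = TRUE),
                        sample.int(1e7, 40), name = paste0("s", 1:40))
  pr <- cis_pairs(cat_r)
  brute <- sum(vapply(split(cat_r$pos, cat_r$chrom),
                      function(p) choose(length(p), 2), 0))
  expect_equal(nrow(pr), brute)
  expect_true(all(pr$pos1 < pr$pos2))
  # each unordered pair appears exactly once
  expect_false(anyDuplicated(paste(pr$chrom, pr$pos1, pr$pos2)) > 0)

  # the mouse-like 97-site preset yields exactly 304 cis pairs
  preset <- mouse_like_cut_sites()
  expect_equal(nrow(preset$sites), 97)
  expect_equal(nrow(cis_pairs(preset$sites)), 304)
})

test_that("pairwise pileup reproduces single snippets and flat maps", {
  # a deterministic random O/E: single snippet equals the raw window
  set.seed(31)
  n <- 200
  M <- matrix(rlnorm(n * n, 0, 0.2), n, n); M <- (M + t(M)) / 2
  oe <- oe_from_matrix(M, 25000)
  pairs <- data.frame(chrom = "chr1", pos1 = 50 * 25000 + 1,
                      pos2 = 149 * 25000 + 1)
  f <- 10 * 25000
  p1 <- pairwise_pileup(oe, pairs, flank = f)
  expect_equal(p1$n_used, 1)
  expect_equal(p1$mean_linear, M[41:61, 140:160])

  # uniform O/E = 1: all cells 1, log2 0
  oeu <- oe_from_matrix(matrix(1, n, n), 25000)
  pairs10 <- data.frame(chrom = "chr1",
                        pos1 = seq(20, 65, by = 5) * 25000,
                        pos2 = seq(120, 165, by = 5) * 25000)
  pu <- pairwise_pileup(oeu, pairs10, flank = f)
  expect_equal(pu$n_used, 10)
  expect_true(all(abs(pu$mean_linear - 1) < 1e-12))
  expect_true(all(abs(pu$mean_log2) < 1e-12))
  expect_equal(pu$enrichment_score, 1)

  # drop rules: near-end and near-diagonal pairs are counted, not used
  bad <- data.frame(chrom = "chr1",
                    pos1 = c(5 * 25000, 100 * 25000),
                    pos2 = c(100 * 25000, 115 * 25000))
  pd <- pairwise_pileup(oe, rbind(pairs, bad), flank = f)
  expect_equal(pd$n_used, 1)
  expect_equal(pd$n_dropped, 2)
  expect_error(pairwise_pileup(oe, bad, flank = f), "no usable snippets")
})

test_that("cluster enrichment score equals the index-set oracle", {
  # flat pileup -> 1; boosted 5x5 center with unit ring -> the boost
  d <- 81
  M1 <- matrix(1, d, d)
  expect_equal(cluster_enrichment_score(M1, resolution = 25000), 1)
  M3 <- M1; ctr <- 41
  M3[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)] <- 3
  expect_equal(cluster_enrichment_score(M3, resolution = 25000), 3)

  # random pileup vs brute-force two-region mean ratio
  set.seed(41)
  Mr <- matrix(rlnorm(d * d, 0, 0.5), d, d)
  cheb <- pmax(abs(row(Mr) - ctr), abs(col(Mr) - ctr))
  oracle <- mean(Mr[cheb <= 2]) / mean(Mr[cheb > 2 & cheb <= 40])
  expect_equal(cluster_enrichment_score(Mr, resolution = 25000), oracle)
})

test_that("planted focal boosts are recovered at pair centers", {
  sites <- site_catalog(rep("chr1", 5), c(4e6, 11e6, 18e6, 25e6, 32e6),
                        name = paste0("s", 1:5))
  cfg <- hic_sim_config(chrom_sizes = c(chr1 = 4e7), bin_size = 25000,
                        cut_sites = sites, beta = 3, n_pairs = 1.2e7,
                        seed = 2)
  oe_d <- observed_over_expected(
    ice_balance(simulate_contact_map(cfg, "damage")))
  pd <- pairwise_pileup(oe_d, cis_pairs(sites))
  expect_equal(pd$n_used, 10)
  ctr <- (nrow(pd$mean_linear) + 1) / 2
  # the boosted focal core: single-cell estimate is noisy, the 5x5 core
  # mean (the quantity the enrichment score uses) is tight
  expect_lt(abs(pd$mean_linear[ctr, ctr] - 3) / 3, 0.15)
  core <- pd$mean_linear[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)]
  expect_lt(abs(mean(core) - 3) / 3, 0.1)
  # control condition carries no boost
  oe_c <- observed_over_expected(
    ice_balance(simulate_contact_map(cfg, "control")))
  pc <- pairwise_pileup(oe_c, cis_pairs(sites))
  expect_gt(pd$enrichment_score - pc$enrichment_score, 0.5)
})

test_that("matched-control resampling obeys all three constraints", {
  sizes <- c(chr1 = 3.2e7, chr2 = 3.2e7)
  sites <- site_catalog(rep(c("chr1", "chr2"), each = 3),
                        rep(c(6e6, 16e6, 26e6), 2), name = paste0("s", 1:6))
  motifs <- site_catalog(rep(c("chr1", "chr2"), each = 6),
                         rep(seq(4e6, 29e6, by = 5e6), 2),
                         name = paste0("m", 1:12))
  cfg <- hic_sim_config(chrom_sizes = sizes, bin_size = 25000, kappa = 0.3,
                        block_bins = 40, n_pairs = 6e6, seed = 8)
  m <- ice_balance(simulate_contact_map(cfg, "control"))
  oe <- observed_over_expected(m)
  m250 <- ice_balance(coarsen(m, 250000))
  gd <- average_track(sim_gene_density(cfg), m250$bins)
  comp <- compartment_eigenvector(observed_over_expected(m250), gd)
  nul <- matched_control_null(sites, motifs, comp, oe, n_resamples = 25,
                              seed = 3)
  expect_equal(length(nul$scores), 25)
  lab_of <- function(chrom, pos) {
    id <- bin_of(comp$ev1$bins, chrom, pos)
    comp$labels[id]
  }
  site_lab <- sort(paste(sites$chrom, lab_of(sites$chrom, sites$pos)))
  for (l in nul$loci) {
    expect_true(all(l$dist >= 125000))                        # constraint 1
    expect_equal(table(l$chrom), table(sites$chrom))          # constraint 2
    expect_equal(sort(paste(l$chrom, lab_of(l$chrom, l$pos))),
                 site_lab)                                    # constraint 3
  }
  # distinct seeds give distinct draws; same master seed reproduces
  expect_false(identical(nul$loci[[1]], nul$loci[[2]]))
  nul2 <- matched_control_null(sites, motifs, comp, oe, n_resamples = 2,
                               seed = 3)
  expect_identical(nul2$loci[[1]], nul$loci[[1]])
})

test_that("the resampling null brackets the true score on a clustering-free map", {
  # compartment-free, loop-free map: site score and null band both sit at 1
  sizes <- c(chr1 = 3.2e7, chr2 = 3.2e7)
  sites <- site_catalog(rep(c("chr1", "chr2"), each = 3),
                        rep(c(6e6, 16e6, 26e6), 2), name = paste0("s", 1:6))
  motifs <- site_catalog(rep(c("chr1", "chr2"), each = 6),
                         rep(seq(4e6, 29e6, by = 5e6), 2),
                         name = paste0("m", 1:12))
  cfg <- hic_sim_config(chrom_sizes = sizes, bin_size = 25000, kappa = 0,
                        n_pairs = 6e6, seed = 8)
  m <- ice_balance(simulate_contact_map(cfg, "control"))
  oe <- observed_over_expected(m)
  m250 <- ice_balance(coarsen(m, 250000))
  gd <- average_track(sim_gene_density(cfg), m250$bins)
  comp <- compartment_eigenvector(observed_over_expected(m250), gd)
  nul <- matched_control_null(sites, motifs, comp, oe, n_resamples = 25,
                              seed = 3)
  true_score <- pairwise_pileup(oe, cis_pairs(sites))$enrichment_score
  expect_lt(abs(true_score - nul$mean), 2 * nul$sd + 1e-9)
  expect_lt(abs(nul$mean - 1), 2 * nul$sd)
})

test_that("oriented CTCF pileups reflect strand and detect extrusion lines", {
  set.seed(51)
  n <- 300
  M <- matrix(rlnorm(n * n, 0, 0.3), n, n); M <- (M + t(M)) / 2
  oe <- oe_from_matrix(M, 5000)
  plus <- site_catalog(rep("chr1", 3), c(60, 150, 240) * 5000, strand = "+")
  minus <- site_catalog(rep("chr1", 3), c(60, 150, 240) * 5000, strand = "-")
  pp <- ctcf_pileup(oe, plus)
  pm <- ctcf_pileup(oe, minus)
  d <- nrow(pp$mean_linear)
  expect_equal(d, 41)
  expect_equal(pm$mean_linear, pp$mean_linear[d:1, d:1])
  expect_error(ctcf_pileup(oe, site_catalog("chr1", 1e6, strand = "*")),
               "oriented")

  # planted one-sided lines: downstream line score exceeds upstream
  anchors <- site_catalog(rep("chr1", 6), seq(3e6, 17e6, length.out = 6),
                          strand = rep(c("+", "-"), 3))
  cfg <- hic_sim_config(chrom_sizes = c(chr1 = 2e7), bin_size = 5000,
                        anchors = anchors, line_boost = 1.8,
                        line_len_bins = 15, n_pairs = 1e7, seed = 9)
  oe_l <- observed_over_expected(
    ice_balance(simulate_contact_map(cfg, "control")))
  pl <- ctcf_pileup(oe_l, anchors)
  expect_gt(pl$line_downstream, pl$line_upstream + 0.1)
})

test_that("convergent pair enumeration and loop score recover planted loops", {
  # alternating + - + - anchors, all separations in range -> 3 pairs
  alt <- site_catalog(rep("chr1", 4), c(1e6, 1.2e6, 1.4e6, 1.6e6),
                      strand = c("+", "-", "+", "-"))
  pr <- convergent_pairs(alt, 25000, 1e6)
  expect_equal(nrow(pr), 3)  # (1,2), (1,4), (3,4); (3,2) is divergent
  # brute-force oracle on a random anchor set
  set.seed(61)
  rnd <- site_catalog(sample(c("chr1", "chr2"), 30, replace = TRUE),
                      sample.int(3e7, 30),
                      strand = sample(c("+", "-"), 30, replace = TRUE))
  pr2 <- convergent_pairs(rnd, 25000, 1e6)
  brute <- 0
  for (a in seq_len(30)) for (b in seq_len(30)) {
    if (rnd$chrom[a] == rnd$chrom[b] && rnd$strand[a] == "+" &&
        rnd$strand[b] == "-") {
      sep <- rnd$pos[b] - rnd$pos[a]
      if (sep >= 25000 && sep <= 1e6) brute <- brute + 1
    }
  }
  expect_equal(nrow(pr2), brute)

  # uniform map scores 1; planted lambda = 2.5 recovered within 10%
  oeu <- oe_from_matrix(matrix(1, 200, 200), 25000)
  anch <- site_catalog(rep("chr1", 4), c(2e6, 2.4e6, 3.2e6, 3.6e6),
                       strand = c("+", "-", "+", "-"))
  lsu <- convergent_loop_score(oeu, anch)
  expect_equal(lsu$loop_score, 1)

  pos <- c(); st <- c()
  for (k in 0:5) {
    c0 <- 5e6 + k * 6e6
    pos <- c(pos, c0, c0 + 3e5 + k * 1e5); st <- c(st, "+", "-")
  }
  an <- site_catalog(rep("chr1", length(pos)), pos, strand = st)
  cfg <- hic_sim_config(chrom_sizes = c(chr1 = 4e7), bin_size = 25000,
                        anchors = an, lambda = 2.5, n_pairs = 8e6, seed = 4)
  oe_l <- observed_over_expected(
    ice_balance(simulate_contact_map(cfg, "control")))
  ls <- convergent_loop_score(oe_l, an)
  expect_equal(ls$n_loops, 6)
  expect_lt(abs(ls$loop_score - 2.5) / 2.5, 0.1)
})

test_that("anchored differential tracks are zero, focal and antisymmetric", {
  n <- 50
  M <- matrix(1, n, n)
  oe_a <- oe_from_matrix(M, 1e6)
  anchor <- list(chrom = "chr1", pos = 25.5e6)
  d0 <- anchored_differential(oe_a, oe_a, anchor)
  expect_true(all(d0$values == 0, na.rm = TRUE))

  M2 <- M; M2[26, 40] <- M2[40, 26] <- 1.5
  oe_b <- oe_from_matrix(M2, 1e6)
  d1 <- anchored_differential(oe_b, oe_a, anchor)
  expect_equal(d1$values[40], 0.5)
  expect_equal(sum(d1$values != 0, na.rm = TRUE), 1)
  d2 <- anchored_differential(oe_a, oe_b, anchor)
  expect_equal(d2$values, -d1$values)

  # masking hides the local-diagonal neighborhood
  dm <- anchored_differential(oe_b, oe_a, anchor, mask_radius = 3e6)
  expect_true(all(is.na(dm$values[23:29])))
  expect_equal(dm$values[40], 0.5)
})
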