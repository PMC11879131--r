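# Mutational-profiling counting, reactivity computation, normalization, and
# GII-vs-PIE divergence statistics.

ref10 <- c(ref = "ACGTACGTAC")

test_that("a single mismatch is counted at its own reference position", {
  rec <- sam_records(qname = "r1", flag = 0L, rname = "ref", pos = 0L,
                     mapq = 60L, cigar = "10M", seq = "ACGTTCGTAC",
                     md = "4A5") # mismatch at offset 4
  mc <- count_mutation_rates(rec, ref10)
  expect_equal(mc$events, c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(mc$depth, rep(1, 10))
})

test_that("a deletion is one event 5' of the deleted base, which is not covered", {
  rec <- sam_records(qname = "r1", flag = 0L, rname = "ref", pos = 0L,
                     mapq = 60L, cigar = "5M1D4M", seq = "ACGTAGTAC",
                     md = "5^C4")
  mc <- count_mutation_rates(rec, ref10)
  expect_equal(which(mc$events == 1) - 1L, 4L) # reference offset 4
  expect_equal(mc$depth, c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1))
})

test_that("mismatches fall back to SEQ-vs-reference comparison without MD", {
  rec <- sam_records(qname = "r1", flag = 0L, rname = "ref", pos = 0L,
                     mapq = 60L, cigar = "10M", seq = "ACGTTCGTAC")
  mc <- count_mutation_rates(rec, ref10)
  expect_equal(which(mc$events == 1) - 1L, 4L)
})

test_that("nearby events on one read merge to the 5'-most position", {
  # mismatches at offsets 4 and 6 are within 2 nt -> one event at 4
  rec <- sam_records(qname = "r1", flag = 0L, rname = "ref", pos = 0L,
                     mapq = 60L, cigar = "10M", seq = "ACGTTCTTAC",
                     md = "4A1G3")
  mc <- count_mutation_rates(rec, ref10)
  expect_equal(sum(mc$events), 1)
  expect_equal(which(mc$events == 1) - 1L, 4L)
  # 3 nt apart -> two events
  rec2 <- sam_records(qname = "r1", flag = 0L, rname = "ref", pos = 0L,
                      mapq = 60L, cigar = "10M", seq = "ACGTTCGAAC",
                      md = "4A2T2")
  expect_equal(sum(count_mutation_rates(rec2, ref10)$events), 2)
})

test_that("empty input, foreign references and low-mapq reads are handled", {
  mc <- count_mutation_rates(sam_records(), ref10)
  expect_equal(mc$events, rep(0, 10))
  expect_equal(mc$depth, rep(0, 10))
  recs <- bind_sam(
    sam_records(qname = "a", flag = 0L, rname = "other", pos = 0L, mapq = 60L,
                cigar = "10M", seq = "*", md = "10"),
    sam_records(qname = "b", flag = 0L, rname = "ref", pos = 0L, mapq = 5L,
                cigar = "10M", seq = "*", md = "10"))
  mc <- count_mutation_rates(recs, ref10)
  expect_equal(sum(mc$depth), 0)
  expect_equal(attr(mc, "n_skipped_other_ref"), 1L)
  expect_equal(attr(mc, "n_excluded_low_mapq"), 1L)
})

mk_counts <- function(events, depth) {
  structure(list(events = events, depth = depth), class = "mutation_counts")
}

test_that("reactivity follows (rate_mod - rate_unt) / rate_den", {
  prof <- compute_reactivity(mk_counts(50, 1000), mk_counts(10, 1000),
                             mk_counts(80, 1000), depth_threshold = 500)
  expect_equal(prof$raw, 0.5) # (0.05 - 0.01) / 0.08
  # null reactivity when modified equals untreated
  prof0 <- compute_reactivity(mk_counts(10, 1000), mk_counts(10, 1000),
                              mk_counts(80, 1000), depth_threshold = 500)
  expect_equal(prof0$raw, 0)
})

test_that("any channel depth below the threshold masks the position", {
  prof <- compute_reactivity(mk_counts(50, 1000), mk_counts(10, 499),
                             mk_counts(80, 1000), depth_threshold = 500)
  expect_false(prof$mask)
  expect_true(is.na(prof$raw))
  # depth exactly at the threshold passes
  prof2 <- compute_reactivity(mk_counts(50, 500), mk_counts(10, 500),
                              mk_counts(80, 500), depth_threshold = 500)
  expect_true(prof2$mask)
})

test_that("raising the depth threshold never unmasks a position", {
  set.seed(7)
  for (i in 1:20) {
    L <- 30
    depths <- lapply(1:3, function(...) sample(0:1500, L, replace = TRUE))
    counts <- lapply(depths, function(d) mk_counts(rbinom(L, d, 0.05), d))
    masks <- lapply(c(200, 500, 800), function(thr)
      compute_reactivity(counts[[1]], counts[[2]], counts[[3]], thr)$mask)
    expect_true(all(masks[[2]] <= masks[[1]]))
    expect_true(all(masks[[3]] <= masks[[2]]))
  }
})

test_that("scaling events and depths together leaves raw reactivity unchanged", {
  set.seed(8)
  d <- sample(600:1200, 40, replace = TRUE)
  ev <- lapply(1:3, function(...) rbinom(40, d, 0.04))
  base <- compute_reactivity(mk_counts(ev[[1]], d), mk_counts(ev[[2]], d),
                             mk_counts(ev[[3]], d))
  scaled <- compute_reactivity(mk_counts(3 * ev[[1]], 3 * d),
                               mk_counts(3 * ev[[2]], 3 * d),
                               mk_counts(3 * ev[[3]], 3 * d))
  expect_equal(scaled$raw, base$raw)
})

test_that("normalization scale is the mean of the 90th-98th percentile band", {
  # hand-built vector: ranks 1-90 = 0.5, 91-98 = 2.0, 99-100 = 10 (outliers).
  # The band between the 90th and 98th percentile is exactly the eight 2.0s,
  # so scale = 2.0 and those positions normalize to 1.0.
  raw <- c(rep(0.5, 90), rep(2.0, 8), rep(10, 2))
  prof <- structure(list(raw = raw, norm = rep(NA_real_, 100),
                         mask = rep(TRUE, 100), depth_threshold = 500),
                    class = "reactivity_profile")
  out <- normalize_reactivity(prof)
  expect_equal(attr(out, "scale"), 2.0)
  expect_equal(out$norm[91], 1.0)
  expect_equal(out$norm[1], 0.25)
  # all-equal positive raw values normalize to 1
  prof2 <- structure(list(raw = rep(1.7, 30), norm = rep(NA_real_, 30),
                          mask = rep(TRUE, 30), depth_threshold = 500),
                     class = "reactivity_profile")
  expect_equal(normalize_reactivity(prof2)$norm, rep(1, 30))
})

test_that("normalization fails on too few positions or a non-positive scale", {
  few <- structure(list(raw = rep(1, 10), norm = rep(NA_real_, 10),
                        mask = rep(TRUE, 10), depth_threshold = 500),
                   class = "reactivity_profile")
  expect_error(normalize_reactivity(few), "normalization failed")
  neg <- structure(list(raw = rep(-1, 30), norm = rep(NA_real_, 30),
                        mask = rep(TRUE, 30), depth_threshold = 500),
                   class = "reactivity_profile")
  expect_error(normalize_reactivity(neg), "normalization failed")
})

# divergence ----------------------------------------------------------------

mk_profile <- function(raw, mask = !is.na(raw)) {
  structure(list(raw = raw, norm = raw, mask = mask, depth_threshold = 500),
            class = "reactivity_profile")
}

toy_profiles <- function(pie_transform = identity) {
  lay <- toy_layout()
  it <- toy_intron()
  L_gii <- nchar(it$sequence)
  set.seed(21)
  g <- runif(L_gii, 0, 2)
  p_raw <- rep(NA_real_, nchar(lay$precursor_sequence))
  mapped <- which(!is.na(lay$gii_map))
  p_raw[mapped] <- pie_transform(g[lay$gii_map[mapped] + 1L])
  list(gii = mk_profile(g), pie = mk_profile(p_raw), layout = lay, intron = it)
}

test_that("identical and offset profiles give r = 1 per domain", {
  tp <- toy_profiles()
  div <- domain_divergence(tp$gii, tp$pie, tp$layout, tp$intron,
                           min_positions = 5)
  expect_equal(div$pearson_r, rep(1, 4), tolerance = 1e-12)
  off <- toy_profiles(function(x) x + 0.3) # location shift leaves r at 1
  div2 <- domain_divergence(off$gii, off$pie, off$layout, off$intron)
  expect_equal(div2$pearson_r, rep(1, 4), tolerance = 1e-12)
})

test_that("domains with too few co-unmasked positions yield a null row", {
  tp <- toy_profiles()
  tp$pie$mask[] <- FALSE
  div <- domain_divergence(tp$gii, tp$pie, tp$layout, tp$intron)
  expect_true(all(is.na(div$pearson_r)))
  expect_true(all(div$n_positions == 0))
})

test_that("per-domain Pearson matches the closed-form formula on a toy domain", {
  g <- c(0.1, 0.4, 0.9, 1.3, 0.2, 0.7, 1.1, 0.5)
  p <- c(0.2, 0.5, 0.8, 1.4, 0.1, 0.6, 2.5, 0.4) # one discordant value
  # textbook Pearson, written out
  r_hand <- sum((g - mean(g)) * (p - mean(p))) /
    sqrt(sum((g - mean(g))^2) * sum((p - mean(p))^2))
  it <- intron_spec("t8", paste(rep("ACGT", 6), collapse = ""),
                    data.frame(label = c("P6", "P9"), start = c(8, 14),
                               end = c(13, 22)))
  lay <- build_pie(it, e1 = c(0, 4), e2 = c(20, 24), goi = "AAAA")
  gp <- rep(NA_real_, 24); gp[15:22] <- g # P9 = GII [14,22)
  pp <- rep(NA_real_, nchar(lay$precursor_sequence))
  pp[map_gii_to_pie(lay, 14:21) + 1L] <- p
  div <- domain_divergence(mk_profile(gp), mk_profile(pp), lay, it)
  expect_equal(div$pearson_r[div$domain == "P9"], r_hand, tolerance = 1e-12)
})

test_that("divergence association recovers a perfect rank concordance", {
  tab <- data.frame(intron = paste0("i", 1:8), domain = "P2",
                    pearson_r = seq(0.9, 0.2, length.out = 8))
  eff <- setNames(seq(10, 80, length.out = 8), paste0("i", 1:8))
  res <- divergence_association(tab, eff)
  expect_equal(res$spearman_rho, 1)
  expect_error(divergence_association(tab[1:3, ], eff), "insufficient groups")
})

test_that("constant efficiencies give a null association with a warning", {
  tab <- data.frame(intron = paste0("i", 1:5), domain = "P9",
                    pearson_r = c(0.9, 0.7, 0.5, 0.3, 0.1))
  eff <- setNames(rep(50, 5), paste0("i", 1:5))
  expect_warning(res <- divergence_association(tab, eff), "degenerate")
  expect_true(is.na(res$spearman_rho))
})

test_that("exact permutation p matches brute-force enumeration at n = 5", {
  tab <- data.frame(intron = paste0("i", 1:5), domain = "P7",
                    pearson_r = c(0.81, 0.62, 0.77, 0.45, 0.70))
  eff <- setNames(c(30, 62, 20, 85, 44), paste0("i", 1:5))
  res <- divergence_association(tab, eff)
  x <- 1 - tab$pearson_r
  y <- unname(eff[tab$intron])
  rho_obs <- cor(rank(x), rank(y))
  # enumerate all 120 orderings of y against fixed x
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y[unlist(p)])))
  p_brute <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(nrow(perms), 120)
  expect_equal(res$p_value, p_brute, tolerance = 1e-12)
})
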