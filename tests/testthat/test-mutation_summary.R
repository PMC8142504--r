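test_that("SNV spectrum collapses to pyrimidine reference classes", {
  maf <- toy_maf(rep("P1", 4), paste0("g", 1:4), rep("Missense_Mutation", 4),
                 ref = c("G", "C", "A", "T"), alt = c("A", "T", "C", "G"))
  sp <- snv_spectrum(maf)
  expect_equal(unname(sp["C>T"]), 2)  # G>A collapses to C>T
  expect_equal(unname(sp["T>G"]), 2)  # A>C collapses to T>G
  expect_equal(sum(sp), 4)
  # 12-variant hand tally
  ref <- c("C", "C", "C", "G", "G", "T", "T", "A", "A", "G", "C", "T")
  alt <- c("A", "G", "T", "A", "T", "A", "C", "G", "T", "C", "T", "G")
  maf2 <- toy_maf(rep("P1", 12), paste0("h", 1:12),
                  rep("Missense_Mutation", 12), ref = ref, alt = alt)
  sp2 <- snv_spectrum(maf2)
  hand <- c("C>A" = 2, "C>G" = 2, "C>T" = 3, "T>A" = 2, "T>C" = 2, "T>G" = 1)
  # per-record classes: C>A, C>G, C>T, G>A=C>T, G>T=C>A, T>A, T>C,
  #                     A>G=T>C, A>T=T>A, G>C=C>G, C>T, T>G
  hand <- c("C>A" = 2, "C>G" = 2, "C>T" = 3, "T>A" = 2, "T>C" = 2, "T>G" = 1)
  expect_equal(as.integer(sp2[names(hand)]), unname(hand))
  expect_equal(sum(sp2), 12)
})

test_that("spectrum is invariant under reverse-complementing every record", {
  co <- default_cohort()
  sp1 <- snv_spectrum(co$maf)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- as.data.frame(co$maf)
  snp <- flipped$variant_type == "SNP"
  flipped$ref_allele[snp] <- comp[flipped$ref_allele[snp]]
  flipped$alt_allele[snp] <- comp[flipped$alt_allele[snp]]
  sp2 <- snv_spectrum(MafTable(flipped))
  expect_equal(sp1, sp2)
})

test_that("per-gene frequencies are per-sample binarized hand counts", {
  lab <- SubtypeAssignment(setNames(c("sub1", "sub1", "sub2", "sub2"),
                                    paste0("P", 1:4)), k = 2)
  maf <- toy_maf(c("P1", "P1", "P1", "P2", "P3", "P3", "P4", "P1", "P2", "P3"),
                 c("TP53", "TP53", "TP53", "TP53", "TP53", "KRAS", "KRAS",
                   "KRAS", "EGFR", "EGFR"),
                 c(rep("Missense_Mutation", 7), "Nonsense_Mutation",
                   "Silent", "Missense_Mutation"))
  land <- summarize_maf(maf, lab)
  f <- land$gene_freq
  # TP53: P1 (3 variants -> once) + P2 in sub1 = 2/2; P3 in sub2 = 1/2
  expect_equal(f$sub1[f$gene == "TP53"], 1)
  expect_equal(f$sub2[f$gene == "TP53"], 0.5)
  # KRAS: P1 in sub1 -> 1/2; P3, P4 in sub2 -> 2/2
  expect_equal(f$sub1[f$gene == "KRAS"], 0.5)
  expect_equal(f$sub2[f$gene == "KRAS"], 1)
  # EGFR: silent record in P2 does not count; P3 counts
  expect_equal(f$sub1[f$gene == "EGFR"], 0)
  expect_equal(f$sub2[f$gene == "EGFR"], 0.5)
  expect_true(all(f$sub1 <= 1 & f$sub2 <= 1))
  # empty MAF gives an empty landscape
  land0 <- summarize_maf(maf[0, , drop = FALSE], lab)
  expect_equal(nrow(land0$gene_freq), 0)
  expect_equal(sum(unlist(land0$class_counts)), 0)
})

test_that("unassigned MAF samples are dropped with a warning", {
  lab <- SubtypeAssignment(setNames(c("sub1", "sub2"), c("P1", "P2")), k = 2)
  maf <- toy_maf(c("P1", "P2", "P9"), c("A1", "A1", "A1"),
                 rep("Missense_Mutation", 3))
  expect_warning(land <- summarize_maf(maf, lab), "without a subtype")
  expect_equal(land$gene_freq$sub1[1], 1)
})

test_that("driver comparison matches closed-form chi-square and Fisher", {
  lab <- SubtypeAssignment(setNames(rep(c("sub1", "sub2"), each = 20),
                                    sprintf("P%02d", 1:40)), k = 2)
  # 8/20 mutated in sub1, 2/20 in sub2 for DRV1
  carriers <- c(sprintf("P%02d", 1:8), sprintf("P%02d", 21:22))
  maf <- toy_maf(carriers, rep("DRV1", 10), rep("Missense_Mutation", 10))
  dc <- driver_compare(maf, lab, c("DRV1", "ABSENT"))
  tab <- matrix(c(8, 12, 2, 18), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((abs(tab - expected) - 0.5)^2 / expected)
  row <- dc[dc$gene == "DRV1", ]
  expect_equal(row$statistic, stat_hand, tolerance = 1e-10)
  expect_equal(row$freq_sub1, 0.4)
  expect_equal(row$freq_sub2, 0.1)
  absent <- dc[dc$gene == "ABSENT", ]
  expect_equal(absent$freq_sub1, 0)
  expect_true(is.na(absent$p))
})

test_that("Fisher fallback matches hypergeometric enumeration", {
  lab <- SubtypeAssignment(setNames(rep(c("sub1", "sub2"), each = 6),
                                    sprintf("Q%02d", 1:12)), k = 2)
  carriers <- c("Q01", "Q02", "Q03", "Q07")  # 3/6 vs 1/6
  maf <- toy_maf(carriers, rep("DRV2", 4), rep("Missense_Mutation", 4))
  dc <- driver_compare(maf, lab, "DRV2")
  expect_equal(dc$method, "fisher")
  # two-sided Fisher p by enumerating all tables with 4 carriers of 12
  probs <- dhyper(0:4, 6, 6, 4)
  obs <- dhyper(3, 6, 6, 4)
  p_hand <- sum(probs[probs <= obs + 1e-12])
  expect_equal(dc$p, p_hand, tolerance = 1e-12)
})

test_that("balanced equal frequencies give chi2 0 and p 1", {
  lab <- SubtypeAssignment(setNames(rep(c("sub1", "sub2"), each = 20),
                                    sprintf("R%02d", 1:40)), k = 2)
  carriers <- c(sprintf("R%02d", 1:10), sprintf("R%02d", 21:30))
  maf <- toy_maf(carriers, rep("DRV3", 20), rep("Missense_Mutation", 20))
  dc <- driver_compare(maf, lab, "DRV3")
  expect_equal(dc$statistic, 0)
  expect_equal(dc$p, 1)
})
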