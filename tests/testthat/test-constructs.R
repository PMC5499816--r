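test_that("IUPAC mismatch counting honours ambiguity classes", {
  expect_equal(iupac_mismatches("CRCGTG", "CACGTG"), 0L)  # A is in R
  expect_equal(iupac_mismatches("CRCGTG", "CGCGTG"), 0L)  # G is in R
  expect_equal(iupac_mismatches("CRCGTG", "CTCGTG"), 1L)  # T is not
  expect_equal(iupac_mismatches("TRCGCATACG", "TACGCATACG"), 0L)
  expect_equal(iupac_mismatches(catac_ebox(), c("CACGTG", "CCCGTG", "AAAAAA")),
               c(0L, 1L, 5L))
  expect_error(iupac_mismatches("CRCGTG", "CACGT"), "length")
})

test_that("consensus patterns stay within the 29-residue motif", {
  expect_equal(catac_core()$offset, 8L)
  expect_equal(catac_ebox()$offset, 19L)
  expect_error(consensus_pattern("bad", "ACGTACGT", 25), "within motif")
  expect_error(consensus_pattern("bad", "ACXT", 1), "non-IUPAC")
})

test_that("printed wild-type enhancers contain four elements each", {
  for (cn in c("slob_4x", "pdp1_4x", "pdp1_pse")) {
    el <- catac_elements(cn)
    expect_equal(nrow(el), 4L, info = cn)
    expect_true(all(el$core_mismatches <= 2), info = cn)
    expect_true(all(nchar(el$element_seq) == 29), info = cn)
    # elements are disjoint on the enhancer
    expect_true(all(el$start[-1] >= el$end[-4]), info = cn)
  }
  # exactly one Pdp1 element carries a canonical E-box; none in Slob
  eboxes <- function(el) substr(el$element_seq, 19, 24)
  expect_equal(sum(eboxes(catac_elements("pdp1_4x")) == "CACGTG"), 1L)
  expect_equal(sum(eboxes(catac_elements("slob_4x")) == "CACGTG"), 0L)
})

test_that("PSE E-boxes replicate the Slob E-box fidelity by design", {
  eboxes <- function(cn) sort(substr(catac_elements(cn)$element_seq, 19, 24))
  expect_equal(eboxes("pdp1_pse"), eboxes("slob_4x"))
})

test_that("mutant constructs carry no recognizable elements", {
  # Pdp1 mutant assembles; its elements are destroyed by the transversions
  expect_equal(nrow(catac_elements("pdp1_mt4x")), 0L)
  # the printed Slob mutant oligos are internally inconsistent and do not
  # assemble by exact complementary overlap; scanned individually they
  # contain no elements either
  slob_mt <- catac_constructs()$slob_mt4x
  expect_error(assemble_enhancer(slob_mt), "overlap")
  for (o in slob_mt) {
    expect_equal(nrow(find_elements(o)), 0L)
  }
})

test_that("construct scores reproduce the printed mismatch tallies", {
  slob <- score_construct(catac_elements("slob_4x"))
  pdp1 <- score_construct(catac_elements("pdp1_4x"))
  expect_equal(slob$canonical_mismatches, 9L)
  expect_equal(pdp1$canonical_mismatches, 4L)
  expect_equal(pdp1$catac_ebox_mismatches, 2L)
  # the Slob CRCGTG tally computes to 7/24 under consistent IUPAC matching
  expect_equal(slob$catac_ebox_mismatches, 7L)
  # Slob has the poorer E-boxes, Pdp1 the better ones
  expect_lt(slob$ebox_score, pdp1$ebox_score)
})

test_that("score totals are conserved and perfect elements score 1", {
  perfect <- rep(consensus_element(), 4)
  sc <- score_construct(perfect)
  expect_equal(sc$core_score, 1)
  expect_equal(sc$ebox_score, 1)
  expect_equal(sc$canonical_mismatches, 0L)
  expect_equal(sc$catac_ebox_mismatches, 0L)

  set.seed(71)
  for (i in 1:5) {
    el <- vapply(1:4, function(j) random_dna(29), character(1))
    sc <- score_construct(el)
    expect_equal(sc$core_matches + 40 * (1 - sc$core_score), 40)
    expect_equal(sc$ebox_matches + sc$catac_ebox_mismatches, 24)
    expect_true(sc$core_score >= 0 && sc$core_score <= 1)
  }
  expect_error(score_construct(rep(consensus_element(), 3)), "exactly 4")
})

test_that("element orientation is normalized to the motif strand", {
  for (cn in c("slob_4x", "pdp1_4x")) {
    enh <- assemble_enhancer(catac_constructs()[[cn]])
    fwd <- find_elements(enh)
    rev <- find_elements(revcomp(enh))
    expect_setequal(fwd$element_seq, rev$element_seq)
    expect_equal(score_construct(fwd), score_construct(rev))
    # mirrored coordinates, flipped orientations
    expect_setequal(nchar(enh) - rev$end, fwd$start)
  }
})

test_that("transversion operator swaps A<->T and C<->G at six residues", {
  el <- consensus_element()
  mut <- apply_transversions(el)
  diffs <- which(strsplit(el, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, c(8L, 10L, 14L, 16L, 21L, 23L))
  # involution: applying twice restores the element
  expect_equal(apply_transversions(mut), el)
  # only A<->T / C<->G swaps occur
  pairs <- paste0(strsplit(el, "")[[1]][diffs], strsplit(mut, "")[[1]][diffs])
  expect_true(all(pairs %in% c("AT", "TA", "CG", "GC")))
  # a consensus element gains exactly 4 core mismatches and >= 1 E-box
  # mismatch (residue 21 is an invariant C, residue 23 an invariant T)
  expect_equal(iupac_mismatches("TRCGCATACG", substr(mut, 8, 17)), 4L)
  expect_gte(iupac_mismatches("CRCGTG", substr(mut, 19, 24)), 1L)
  expect_error(apply_transversions(el, positions = 30), "out of range")
})

test_that("wild-type elements mutate into core-unrecognizable elements", {
  for (cn in c("slob_4x", "pdp1_4x")) {
    for (el in catac_elements(cn)$element_seq) {
      mut <- apply_transversions(el)
      expect_equal(sum(strsplit(el, "")[[1]] != strsplit(mut, "")[[1]]), 6L)
      expect_gt(iupac_mismatches("TRCGCATACG", substr(mut, 8, 17)), 2L)
    }
  }
})

test_that("duplex assembly reconstructs sequences from sticky-ended oligos", {
  # two exact reverse complements collapse to the first oligo
  a <- "ACGTACGTACGTACGT"
  expect_equal(as.character(assemble_enhancer(c(a, revcomp(a)))), a)

  # a random sequence split into two duplexes; the first duplex's bottom
  # strand runs 15 bases past its top strand, leaving the sticky end that
  # recruits the second duplex (as in the printed oligo sets)
  set.seed(81)
  full <- random_dna(120)
  top1 <- substr(full, 1, 70)
  bot1 <- revcomp(substr(full, 1, 85))
  top2 <- substr(full, 71, 120)
  bot2 <- revcomp(substr(full, 86, 120))
  out <- assemble_enhancer(c(top1, bot1, top2, bot2))
  expect_equal(as.character(out), full)
  expect_equal(attr(out, "overlaps"), c(70L, 15L, 35L))

  expect_error(assemble_enhancer(c(a, random_dna(30))), "overlap")
  expect_error(assemble_enhancer(a), "at least 2")
})

test_that("random sequence yields the binomially expected element count", {
  # closed form: P(window core matches TRCGCATACG with <= 1 mismatch) under
  # uniform bases; per-position match probabilities 1/2 (R) or 1/4
  p_match <- c(rep(1 / 4, 1), 1 / 2, rep(1 / 4, 8))  # T,R,C,G,C,A,T,A,C,G
  p0 <- prod(p_match)
  p1 <- p0 * sum((1 - p_match) / p_match)
  L <- 500
  expected <- 2 * (L - 29 + 1) * (p0 + p1)
  set.seed(82)
  counts <- vapply(1:200, function(i) {
    nrow(find_elements(random_dna(L), max_core_mismatch = 1))
  }, numeric(1))
  mc_se <- sqrt(expected / 200)   # Poisson-scale Monte-Carlo error
  expect_lt(abs(mean(counts) - expected), 4 * mc_se + 0.01)
})
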