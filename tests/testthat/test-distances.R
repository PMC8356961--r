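test_that("pair_counts classifies transitions, transversions and deletions", {
  pc <- pair_counts("ACGT", "ACGT")
  expect_equal(pc$n, 4); expect_equal(pc$p, 0)
  pc <- pair_counts("ACGT", "GCGT")
  expect_equal(pc$p, 0.25); expect_equal(pc$P1, 0.25); expect_equal(pc$Q, 0)
  pc <- pair_counts("AC-T", "ACGT")
  expect_equal(pc$n, 3)
  pc <- pair_counts("ACNT", "ACGT")   # ambiguity excluded like a gap
  expect_equal(pc$n, 3)
  expect_error(pair_counts("--", "AC"), "no comparable sites")
  expect_error(pair_counts("ACG", "AC"), "length")
})

test_that("nucleotide estimators match the closed forms on an exact grid", {
  for (n in c(100L)) for (nP1 in c(0L, 4L, 10L)) for (nP2 in c(0L, 5L)) {
    for (nQ in c(0L, 3L, 8L)) {
      pr <- pair_with_counts(n, nP1, nP2, nQ)
      pc <- pair_counts(pr$s1, pr$s2)
      expect_equal(pc$P1, nP1 / n)
      expect_equal(pc$P2, nP2 / n)
      expect_equal(pc$Q, nQ / n)
      p <- (nP1 + nP2 + nQ) / n
      pi <- rep(0.25, 4)
      expect_equal(nt_distance(pr$s1, pr$s2, "JC"), oracle_jc(p),
                   tolerance = 1e-9)
      expect_equal(nt_distance(pr$s1, pr$s2, "K2P"),
                   oracle_k2p((nP1 + nP2) / n, nQ / n), tolerance = 1e-9)
      expect_equal(nt_distance(pr$s1, pr$s2, "F81", pi = pi),
                   oracle_f81(p, pi), tolerance = 1e-9)
      if (p > 0) {
        expect_equal(nt_distance(pr$s1, pr$s2, "TN93", pi = pi),
                     oracle_tn93(nP1 / n, nP2 / n, nQ / n, pi),
                     tolerance = 1e-9)
      }
      expect_equal(nt_distance(pr$s1, pr$s2, "pdist"), p)
      expect_equal(nt_distance(pr$s1, pr$s2, "raw"), p)
    }
  }
  expect_error(nt_distance("AC", "AC", "GTR"), "invalid")
})

test_that("textbook worked values evaluate correctly", {
  pr <- pair_with_counts(100, 0, 0, 0)
  s2 <- paste0(strrep("G", 30), substr(pr$s1, 31, 100))
  s1 <- paste0(strrep("A", 30), substr(pr$s1, 31, 100))
  expect_equal(nt_distance(s1, s2, "JC"), oracle_jc(0.3), tolerance = 1e-12)
  expect_equal(oracle_jc(0.3), 0.3831192, tolerance = 1e-6)
  expect_equal(oracle_k2p(0.1, 0.05), 0.1701812, tolerance = 1e-6)
})

test_that("every closed-form estimator agrees with ape::dist.dna", {
  set.seed(31)
  L <- 600
  base <- sample(c("A", "C", "G", "T"), L, TRUE, prob = c(.35, .15, .2, .3))
  mutate <- function(x, rate) {
    i <- which(stats::runif(L) < rate)
    x[i] <- sample(c("A", "G", "C", "T", "A", "G"), length(i), TRUE)
    x
  }
  seqs <- vapply(c(0, .05, .12, .22, .3), function(r) {
    paste(mutate(base, r), collapse = "")
  }, character(1))
  a <- alignment(paste0("s", 1:5), seqs)
  dn <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(a$seqs), "")))
  rownames(dn) <- a$names
  models <- rbind(c("JC", "JC69"), c("K2P", "K80"), c("F81", "F81"),
                  c("F84", "F84"), c("TN93", "TN93"), c("pdist", "raw"))
  for (i in seq_len(nrow(models))) {
    mine <- nt_distance_matrix(a, models[i, 1])
    ref <- as.matrix(ape::dist.dna(dn, model = models[i, 2],
                                   pairwise.deletion = TRUE))
    expect_equal(unclass(mine), ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("model nesting holds: F81 -> JC and TN93 -> K2P at equal frequencies", {
  # equal base frequencies by construction
  s1 <- strrep("ACGT", 50)
  # A<->G and C<->T swaps: composition preserved, one transition of each kind
  s2 <- paste0("GTAC", strrep("ACGT", 49))
  a <- alignment(c("x", "y"), c(s1, s2))
  jc <- nt_distance_matrix(a, "JC"); f81 <- nt_distance_matrix(a, "F81")
  expect_equal(unclass(jc), unclass(f81), tolerance = 1e-9)
  k2p <- nt_distance_matrix(a, "K2P"); tn <- nt_distance_matrix(a, "TN93")
  pc <- pair_counts(s1, s2)
  expect_equal(pc$P1, pc$P2)                 # symmetric construction
  expect_equal(unclass(k2p), unclass(tn), tolerance = 1e-9)
})

test_that("estimators are zero at p = 0 and increase with divergence", {
  for (model in c("JC", "K2P", "F81", "F84", "TN93")) {
    prev <- -1
    for (k in c(0L, 2L, 6L, 12L, 20L)) {
      pr <- pair_with_counts(100, k, 0, max(0L, k %/% 2L))
      d <- nt_distance(pr$s1, pr$s2, model, pi = rep(0.25, 4))
      if (k == 0L) expect_equal(d, 0)
      expect_gt(d, prev)
      prev <- d
    }
  }
})

test_that("saturation yields +Inf and the phylip writer substitutes 20.0", {
  s1 <- strrep("A", 40); s2 <- strrep("G", 40)
  expect_warning(d <- nt_distance(s1, s2, "JC"), "saturated")
  expect_identical(d, Inf)
  a <- alignment(c("x", "y"), c(s1, s2))
  dm <- suppressWarnings(nt_distance_matrix(a, "JC"))
  expect_message(txt <- write_phylip_matrix(dm), "sentinel")
  m <- read_phylip_matrix(text = txt)
  expect_equal(m["x", "y"], 20.0)
})

test_that("distance matrices are exactly symmetric with zero diagonal", {
  a <- simulate_pair("JC", 0.2, 300, seed = 4)
  a <- alignment(c(a$names, "s3"), c(a$seqs, a$seqs[1]))
  for (dm in list(nt_distance_matrix(a, "TN93"),
                  prot_distance_matrix(translate(a), "WAG"))) {
    expect_identical(unclass(dm), t(unclass(dm)))
    expect_true(all(diag(dm) == 0))
  }
})

test_that("ML distance under the uniform model equals the Poisson correction", {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  L <- 2000
  for (p in seq(0.01, 0.85, by = 0.12)) {
    k <- round(L * p)
    v <- rep(aa, length.out = L)
    w <- v
    w[seq_len(k)] <- aa[match(v[seq_len(k)], aa) %% 20 + 1]
    a <- alignment(c("x", "y"), c(paste(v, collapse = ""),
                                  paste(w, collapse = "")),
                   alphabet = "amino-acid")
    d <- prot_distance_matrix(a, "uniform")[1, 2]
    expect_equal(d, oracle_poisson20(k / L), tolerance = 1e-6)
  }
})

test_that("empirical-model ML distances agree with phangorn::dist.ml", {
  a <- simulate_pair("WAG", 0.25, 1500, seed = 12)
  pd <- phangorn::phyDat(setNames(strsplit(a$seqs, ""), a$names), type = "AA")
  for (pair in list(c("WAG", "WAG"), c("LG", "LG"), c("JTT", "JTT"),
                    c("DAYHOFF", "Dayhoff"), c("MTREV", "mtREV24"))) {
    mine <- prot_distance_matrix(a, pair[1])[1, 2]
    ref <- as.matrix(phangorn::dist.ml(pd, model = pair[2]))[1, 2]
    expect_equal(mine, ref, tolerance = 1e-4)
  }
  ident <- alignment(c("x", "y"), c("MKVLW", "MKVLW"), alphabet = "amino-acid")
  expect_equal(prot_distance_matrix(ident, "LG")[1, 2], 0)
  expect_error(prot_distance_matrix(ident, "NOSUCH"), "unknown protein model")
})
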