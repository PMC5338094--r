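test_that("K2P distance matches the closed form and handles gaps", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  res <- k2p_distance(a, b)
  expect_equal(res$d, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(round(res$d, 6), 0.111572)
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0)
  expect_equal(res$sites_used, 100L)

  same <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(same$d, 0)

  # the only difference sits in a gapped column: pairwise deletion removes it
  gapped <- k2p_distance("ACGTACG-", "ACGTACGT")
  expect_equal(gapped$d, 0)
  expect_equal(gapped$sites_used, 7L)

  expect_error(k2p_distance("AAAA", "GGGG"), "saturated")
  expect_error(k2p_distance("----", "AAAA"), "no comparable sites")
})

test_that("distance matrices are symmetric and match a hand count", {
  three <- aln_tbl(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  dm0 <- distance_matrix(three)
  expect_true(all(dm0$d == 0))

  # printed 10-site toy, counted by hand:
  # s1 ACGTACGTAC / s2 GCGTACGTAC (1 ts) / s3 ACATACGAAC (1 ts + 1 tv)
  toy <- aln_tbl(c(s1 = "ACGTACGTAC", s2 = "GCGTACGTAC", s3 = "ACATACGAAC"))
  dm <- distance_matrix(toy)
  expect_equal(dm$P[1, 2], 0.1)
  expect_equal(dm$Q[1, 2], 0)
  expect_equal(dm$d[1, 2], -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(dm$P[1, 3], 0.1)
  expect_equal(dm$Q[1, 3], 0.1)
  expect_equal(dm$d[1, 3],
               -0.5 * log(1 - 0.2 - 0.1) - 0.25 * log(1 - 0.2),
               tolerance = 1e-12)
  expect_equal(dm$d, t(dm$d))
})

test_that("K2P agrees with ape's independent implementation", {
  fam <- simulate_gene_family(root_length = 400, seed = 55)
  dm <- distance_matrix(fam)
  chars <- do.call(rbind, strsplit(fam$seq, ""))
  rownames(chars) <- fam$id
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(chars), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$d, ref[fam$id, fam$id], tolerance = 1e-10)
})

test_that("K2P dominates the p-distance and converges to it at low divergence", {
  withr::with_seed(14, {
    for (k in 1:10) {
      L <- 200
      a <- random_dna(L)
      x <- strsplit(a, "")[[1]]
      nmut <- sample(1:30, 1)
      idx <- sample(L, nmut)
      for (i in idx) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
      b <- paste(x, collapse = "")
      res <- k2p_distance(a, b)
      pdist <- mean(strsplit(a, "")[[1]] != x)
      expect_gte(res$d, pdist - 1e-12)
      if (pdist < 0.02) expect_equal(res$d, pdist, tolerance = 0.01)
    }
  })
})

test_that("NJ solves the 3-taxon case with the three-point formulas", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  cp <- stats::cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cp, d, tolerance = 1e-12)
  # v_a = (5 + 9 - 8)/2 = 3
  expect_equal(tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")], 3)
})

test_that("NJ recovers the quartet split and internal branch of an additive matrix", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, byrow = TRUE, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_equal(stats::cophenetic(tr)[labs, labs], d, tolerance = 1e-12)
  # the AB|CD split must be present with internal branch length 1
  internal <- tr$edge.length[tr$edge[, 1] > 4 & tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("NJ topology is invariant to input label order", {
  case <- withr::with_seed(60, random_additive_case(7))
  perm <- withr::with_seed(61, sample(rownames(case$dm)))
  t1 <- nj_tree(case$dm)
  t2 <- nj_tree(case$dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("NJ is exact on random additive matrices and agrees with ape", {
  withr::with_seed(70, {
    for (k in 1:20) {
      n <- sample(4:12, 1)
      case <- random_additive_case(n)
      tr <- nj_tree(case$dm)
      expect_equal(as.numeric(ape::dist.topo(tr, case$tree)), 0)
      expect_lt(max(abs(stats::cophenetic(tr)[rownames(case$dm), rownames(case$dm)] -
                          case$dm)), 1e-9)
      # independent implementation route
      expect_equal(as.numeric(ape::dist.topo(ape::nj(case$dm), tr)), 0)
    }
  })
})

test_that("NJ matches exhaustive topology enumeration for small trees", {
  withr::with_seed(80, {
    for (k in 1:5) {
      n <- sample(5:6, 1)
      case <- random_additive_case(n)
      tr <- nj_tree(case$dm)
      # enumeration oracle: the unique topology whose best additive fit is exact
      all_tops <- phangorn::allTrees(n, rooted = FALSE,
                                     tip.label = rownames(case$dm))
      resid <- vapply(all_tops, function(top) {
        fit <- phangorn::nnls.tree(case$dm, top, method = "unrooted")
        max(abs(stats::cophenetic(fit)[rownames(case$dm), rownames(case$dm)] -
                  case$dm))
      }, numeric(1))
      best <- all_tops[[which.min(resid)]]
      expect_lt(min(resid), 1e-6)
      expect_equal(as.numeric(ape::dist.topo(tr, best)), 0)
    }
  })
})

test_that("degenerate all-zero distances give an unresolved star", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_equal(tr$Nnode, 1)
})

test_that("bootstrap supports are reproducible and leaf-order invariant", {
  fam <- simulate_gene_family(n_paralogs = 2, root_length = 300, seed = 91)
  b1 <- bootstrap_support(fam, n_replicates = 100, seed = 7)
  b2 <- bootstrap_support(fam, n_replicates = 100, seed = 7)
  expect_identical(b1$node.label, b2$node.label)

  perm <- withr::with_seed(92, sample(nrow(fam)))
  b3 <- bootstrap_support(fam[perm, ], n_replicates = 100, seed = 7)
  # same bipartitions must get the same supports, whatever the input order
  key <- function(tr) {
    bp <- segdupr:::bipartitions(tr, sort(tr$tip.label))
    sort(paste(bp[!is.na(bp) & tr$node.label != ""],
               tr$node.label[!is.na(bp) & tr$node.label != ""]))
  }
  expect_identical(key(b1), key(b3))
})

test_that("a long internal branch earns maximal bootstrap support", {
  # two tight clusters separated by a long branch
  fam <- simulate_gene_family(n_paralogs = 2, root_length = 500,
                              subst_rate = 0.04, duplication_depth = 6,
                              speciation_depth = 0.5, seed = 95)
  bt <- bootstrap_support(fam, n_replicates = 100, seed = 8)
  sup <- suppressWarnings(as.integer(bt$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("identical sequences give an unresolved tree with no supports", {
  same <- aln_tbl(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT",
                    d = "ACGTACGT"))
  bt <- bootstrap_support(same, n_replicates = 10, seed = 1)
  expect_equal(bt$Nnode, 1)
  expect_true(all(bt$node.label == ""))
})

test_that("concerted statistic reproduces hand-computed W, B and ratio", {
  labs <- c("h.P1", "h.P2", "c.P1", "c.P2")
  d <- matrix(0.05, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["h.P1", "h.P2"] <- d["h.P2", "h.P1"] <- 0.01
  d["c.P1", "c.P2"] <- d["c.P2", "c.P1"] <- 0.01
  dm <- structure(list(labels = labs, d = d, P = d, Q = d,
                       sites_used = matrix(100, 4, 4)), class = "k2p_dist")
  cs <- concerted_stat(dm, species = c("h", "h", "c", "c"))
  expect_equal(cs$W, 0.01)
  expect_equal(cs$B, 0.05)
  expect_equal(cs$ratio, 0.2)
  expect_true(all(cs$monophyly))

  # all distances equal -> ratio 1
  d2 <- matrix(0.03, 4, 4, dimnames = list(labs, labs)); diag(d2) <- 0
  dm2 <- structure(list(labels = labs, d = d2, P = d2, Q = d2,
                        sites_used = matrix(100, 4, 4)), class = "k2p_dist")
  expect_equal(concerted_stat(dm2, species = c("h", "h", "c", "c"))$ratio, 1)
})

test_that("concerted statistic validates its inputs", {
  labs <- c("h.P1", "c.P1", "g.P1")
  d <- matrix(0.05, 3, 3, dimnames = list(labs, labs)); diag(d) <- 0
  dm <- structure(list(labels = labs, d = d, P = d, Q = d,
                       sites_used = matrix(10, 3, 3)), class = "k2p_dist")
  expect_error(concerted_stat(dm, species = c("h", "c", "g")),
               "no within-species pairs")
  expect_error(concerted_stat(dm, species = c("h", "h", "h")),
               "at least 2 species")
})

test_that("tidy and glance summarize the concerted statistic", {
  fam <- simulate_gene_family(gene_conversion_rate = 5, seed = 99)
  cs <- concerted_stat(fam)
  td <- tidy(cs)
  expect_equal(nrow(td), 2)
  expect_setequal(td$species, c("speciesA", "speciesB"))
  gl <- glance(cs)
  expect_lt(gl$ratio, 1)
  expect_equal(gl$n_within_pairs, 12L)
})
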