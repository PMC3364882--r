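# engineered panel: a query plus strains at controlled per-fragment identity
mosaic_fixture <- function(n_frag = 8, frag = 1000L) {
  set.seed(80)
  q <- rand_seq(n_frag * frag)
  mut_per_frag <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (f in seq(0, nchar(s) - frag, by = frag)) {
      # keep mutations isolated and clear of fragment edges so each one
      # aligns as exactly one mismatch column
      pos <- f + seq(100, 900, length.out = k)
      for (p in pos) v[p + 1] <- setdiff(BASES, v[p + 1])[1]
    }
    paste(v, collapse = "")
  }
  list(query = dss(q, nm = "q1"),
       panel = list(lab1 = dss(q, nm = "g"),
                    oth1 = dss(mut_per_frag(q, 15), nm = "g"),
                    ind1 = dss(mut_per_frag(q, 30), nm = "g")),
       group_map = data.frame(strain = c("lab1", "oth1", "ind1"),
                              group = c("lab", "other", "industrial")))
}

test_that("mosaic channels hit their documented endpoints exactly", {
  fx <- mosaic_fixture()
  mos <- paint_mosaic(fx$query, fx$panel, fx$group_map)
  # identical genome -> identity 1.0 -> channel 1.0
  expect_true(all(mos$identity_lab == 1))
  expect_true(all(mos$channel_lab == 1))
  # 15 mismatches / 1000 bp -> identity 0.985 -> channel 0.5 (midpoint)
  expect_true(all(abs(mos$channel_other - 0.5) < 1e-9))
  # 30 mismatches -> identity 0.970 -> channel 0.0
  expect_true(all(mos$identity_industrial == 0.97))
  expect_true(all(mos$channel_industrial == 0))
  expect_error(paint_mosaic(fx$query, fx$panel, fx$group_map, fragment = 50),
               ">= 100")
})

test_that("mosaic group identity is order-free and self-panels saturate", {
  fx <- mosaic_fixture(n_frag = 4)
  panel <- c(fx$panel, list(oth2 = fx$panel$ind1))
  gm <- rbind(fx$group_map,
              data.frame(strain = "oth2", group = "other"))
  m1 <- paint_mosaic(fx$query, panel, gm)
  panel_rev <- panel[c("oth2", "ind1", "oth1", "lab1")]
  m2 <- paint_mosaic(fx$query, panel_rev, gm)
  expect_equal(m1$identity_other, m2$identity_other)
  # a panel containing the query itself paints that group at 1.0 everywhere
  expect_true(all(m1$channel_lab == 1))
})

test_that("coverage distance is a proper dissimilarity on its endpoints", {
  set.seed(81)
  a <- dss(rand_seq(20000), nm = "c1")
  b <- dss(rand_seq(20000), nm = "c1")
  expect_equal(coverage_distance(a, a), 0)
  expect_equal(coverage_distance(a, b), 1)
  ab <- coverage_distance(a, b)
  expect_equal(ab, coverage_distance(b, a))
})

test_that("coverage distance grows with simulated divergence", {
  plan <- simulation_plan(seed = 2, n_chromosomes = 1, chromosome_length = 60000,
                          n_genes = 20, n_transposons = c(Ty1 = 0),
                          n_tandem_repeat_loci = 3, indel_count = 5,
                          delete_genes = 0, large_deletion_specs = list(),
                          duplication_specs = list(),
                          excised_transposon_count = 0,
                          unique_insertion_specs = integer(0),
                          dropout_specs = list())
  ref <- generate_reference(plan)
  derive <- function(rate, sd) {
    p <- plan; p$seed <- sd; p$n_snvs <- round(rate * 60000)
    mutate_genome(ref, p)$seqs
  }
  d1 <- coverage_distance(ref$seqs, derive(0.005, 101))
  d2 <- coverage_distance(ref$seqs, derive(0.02, 102))
  d3 <- coverage_distance(ref$seqs, derive(0.05, 103))
  expect_true(d1 < d2 && d2 < d3)
  expect_gt(d1, 0)
})

test_that("UPGMA reproduces hand-worked heights and validates input", {
  # two taxa at distance 0.4 -> a cherry with both branches 0.2
  D2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(D2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  # three taxa: d(A,B)=2, d(A,C)=d(B,C)=6 -> ((A:1,B:1):2,C:3)
  D3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(D3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 6)
  expect_equal(cp["B", "C"], 6)
  expect_true(ape::is.ultrametric(t3, tol = 1e-9))
  # branch to C is 3; internal branch above the (A,B) cherry is 2
  cherry_depth <- t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "A")]
  expect_equal(cherry_depth, 1)

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(upgma(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
})

test_that("UPGMA is an exact fixed point on ultrametric matrices", {
  set.seed(82)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    tr <- ape::rcoal(n)          # ultrametric random tree
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    out <- upgma(D)
    cp <- ape::cophenetic.phylo(out)[rownames(D), colnames(D)]
    expect_equal(cp, D, tolerance = 1e-8)
    expect_true(ape::is.ultrametric(out, tol = 1e-9))
  }
})

test_that("UPGMA agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  n <- 6
  M <- matrix(runif(n * n, 0.2, 1), n, n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  dimnames(D) <- list(letters[1:n], letters[1:n])
  mine <- upgma(D)
  theirs <- phangorn::upgma(as.dist(D))
  expect_equal(ape::cophenetic.phylo(mine)[letters[1:n], letters[1:n]],
               ape::cophenetic.phylo(theirs)[letters[1:n], letters[1:n]],
               tolerance = 1e-8)
})

test_that("distance matrices feed the tree end to end", {
  set.seed(84)
  base <- rand_seq(15000)
  near <- mutate_positions(base, sample(15000, 75))
  far <- mutate_positions(base, sample(15000, 600))
  genomes <- list(A = dss(base, nm = "c"), B = dss(near, nm = "c"),
                  C = dss(far, nm = "c"))
  D <- distance_matrix(genomes)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  tr <- upgma(D)
  # A and B (0.5% apart) must be the cherry, C the outgroup
  cp <- ape::cophenetic.phylo(tr)
  expect_lt(cp["A", "B"], cp["A", "C"])
  expect_lt(cp["A", "B"], cp["B", "C"])
})
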