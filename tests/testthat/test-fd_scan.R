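test_that("score_site reproduces hand-computed Welch contrasts", {
  part <- manual_partition(paste0("a", 1:4), paste0("b", 1:4), "o1")

  # identical residues everywhere: means equal, score 0
  col <- stats::setNames(rep("A", 9), c(paste0("a", 1:4), paste0("b", 1:4), "o1"))
  s <- score_site(col, part)
  expect_equal(s$xbar_a, 4)
  expect_equal(s$xbar_b, 4)
  expect_equal(s$fd_score, 0)

  # clade A = {W,W,W,F}, clade B = {A,A,A,S}, outgroup = {W}
  col <- stats::setNames(c("W", "W", "W", "F", "A", "A", "A", "S", "W"),
                         c(paste0("a", 1:4), paste0("b", 1:4), "o1"))
  s <- score_site(col, part)
  expect_equal(s$xbar_a, 8.5)    # scores 11, 11, 11, 1
  expect_equal(s$var_a, 25)
  expect_equal(s$xbar_b, -3)     # scores -3, -3, -3, -3
  expect_equal(s$var_b, 0)
  expect_equal(s$n_a, 4); expect_equal(s$n_b, 4)
  expect_equal(s$fd_score, 4.6)  # |8.5 - (-3)| / 2.5

  # all-gap outgroup: not scorable
  col["o1"] <- "-"
  expect_null(score_site(col, part))
})

test_that("score_partition matches the brute-force pair oracle on random columns", {
  set.seed(31)
  B <- blosum62()
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    na <- sample(1:(n - 2), 1)
    nb <- sample(1:(n - na - 1), 1)
    ids <- paste0("s", seq_len(n))
    part <- manual_partition(ids[1:na], ids[(na + 1):(na + nb)],
                             ids[(na + nb + 1):n])
    L <- 25
    m <- matrix(sample(c(AA20, "-"), n * L, replace = TRUE,
                       prob = c(rep(1, 20), 4)),
                n, L, dimnames = list(ids, NULL))
    df <- score_partition(toy_group(apply(m, 1, paste, collapse = "")), part)
    for (j in seq_len(L)) {
      o <- oracle_fd_score(m[, j], part$clade_a, part$clade_b, part$outgroup, B)
      if (is.na(o)) {
        expect_false(df$scorable[j])
      } else {
        expect_equal(df$fd_score[j], o, tolerance = 1e-10)
      }
    }
  }
})

test_that("scores are invariant to within-set order and to swapping the clades", {
  set.seed(13)
  ids <- paste0("s", 1:12)
  seqs <- stats::setNames(
    replicate(12, paste(sample(AA20, 30, replace = TRUE), collapse = "")), ids)
  g <- toy_group(seqs)
  p1 <- manual_partition(ids[1:4], ids[5:8], ids[9:12])
  p2 <- manual_partition(sample(ids[1:4]), sample(ids[5:8]), sample(ids[9:12]))
  p3 <- manual_partition(ids[5:8], ids[1:4], ids[9:12])  # swapped clades
  f1 <- score_partition(g, p1)$fd_score
  expect_equal(score_partition(g, p2)$fd_score, f1)
  expect_equal(score_partition(g, p3)$fd_score, f1)
})

test_that("the C++ null scorer agrees with the R scorer on simulated alignments", {
  # dual-route guard: the pooled null scores must equal scoring the same
  # simulated alignment with the reference R implementation
  tr <- root_tree(ape::read.tree(
    text = "(((a1:.1,a2:.1):.1,(a3:.1,a4:.1):.1):.2,((b1:.1,b2:.1):.3,(o1:.1,o2:.1):.4):.05);"))
  part <- enumerate_testable_nodes(tr, min_clade = 2)[[1]]
  g <- toy_group(stats::setNames(rep(strrep("A", 40), 8),
                                 c(paste0("a", 1:4), "b1", "b2", "o1", "o2")))
  null <- suppressWarnings(
    calibrate_null(g, tr, part, seed = 5, n_min = 3, batch_size = 1,
                   max_replicates = 3, sim_length = 40))
  set.seed(5)
  model <- rate_model()
  pooled_r <- unlist(lapply(1:3, function(i) {
    aln <- evolve_alignment(tr, 40, model)
    score_partition(toy_group(apply(aln, 1, paste, collapse = "")), part)$fd_score
  }))
  expect_equal(null$scores, pooled_r, tolerance = 1e-10)
})

test_that("null calibration is deterministic and concentrated near zero on a star-like tree", {
  g <- toy_group(stats::setNames(rep(strrep("A", 60), 10), paste0("s", 1:10)))
  star <- ape::read.tree(text = paste0(
    "((((s1:.2,s2:.2):1e-9,(s3:.2,s4:.2):1e-9):1e-9,",
    "((s5:.2,s6:.2):1e-9,(s7:.2,s8:.2):1e-9):1e-9):1e-9,(s9:.2,s10:.2):1e-9);"))
  part <- enumerate_testable_nodes(star)[[1]]
  n1 <- suppressWarnings(calibrate_null(g, star, part, seed = 8,
                                        n_min = 100, max_replicates = 100))
  n2 <- suppressWarnings(calibrate_null(g, star, part, seed = 8,
                                        n_min = 100, max_replicates = 100))
  expect_identical(n1$scores, n2$scores)
  expect_lt(median(n1$scores), 1)
  expect_equal(n1$n_replicates, 100L)
  expect_s3_class(n1, "null_distribution")
})

test_that("unconverged calibrations warn with a dedicated condition class", {
  g <- toy_group(stats::setNames(rep(strrep("A", 30), 9),
                                 c(paste0("a", 1:4), paste0("b", 1:4), "o1")))
  tr <- ape::read.tree(text = paste0(
    "((((a1:.3,a2:.3):.2,(a3:.3,a4:.3):.2):.2,",
    "((b1:.3,b2:.3):.2,(b3:.3,b4:.3):.2):.2):.1,o1:.6);"))
  part <- enumerate_testable_nodes(tr)[[1]]
  expect_warning(
    calibrate_null(g, tr, part, seed = 2, n_min = 50, batch_size = 10,
                   max_replicates = 60),
    class = "fdscan_unconverged")
})

test_that("empirical p-values follow the add-one tail formula", {
  null <- seq(0, 99.8, by = 0.1)   # 999 null scores
  expect_equal(site_pvalues(100, null), 1 / 1000)
  expect_equal(site_pvalues(0, null), 1)            # score 0 never beats the null
  p <- site_pvalues(c(5, 50, 99.85), null)
  expect_true(all(diff(p) < 0))                     # monotone in the score
  # ties count: #{null >= 50} = 499
  expect_equal(site_pvalues(50, null), (1 + 499) / 1000)
  expect_error(site_pvalues(1, numeric(0)), "empty null")
})

test_that("BH correction matches the hand example and the step-up oracle", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(r$qvalues, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(r$significant, 1:3)
  expect_equal(fdr_correct(rep(1, 10))$significant, integer(0))

  set.seed(17)
  for (i in 1:50) {
    p <- stats::runif(sample(3:80, 1))
    expect_lt(max(abs(fdr_correct(p)$qvalues - oracle_bh(p))), 1e-14)
  }
})

test_that("branch calls require at least one significant site", {
  part <- manual_partition(paste0("a", 1:4), paste0("b", 1:4), "o1")
  expect_false(call_branch(part, integer(0))$is_fd)
  expect_true(call_branch(part, 7L)$is_fd)
  b <- call_branch(part, c(2L, 9L, 14L), group_id = "g1")
  expect_equal(b$significant_sites, c(2L, 9L, 14L))
  expect_equal(b$group_id, "g1")
})

test_that("planted radical sites dominate the scan of a divergent group", {
  d <- make_divergent_group(k_sites = 5, seed = 424)
  sc <- suppressWarnings(scan_group(d$group, seed = 42, n_min = 300,
                                    max_replicates = 300))
  found <- FALSE
  for (p in sc$partitions) {
    if (setequal(c(p$clade_a, p$clade_b), c(d$truth$clade_a, d$truth$clade_b))) {
      found <- TRUE
      ss <- sc$sites[sc$sites$node_id == p$node_id, ]
      rk <- rank(-ss$fd_score, ties.method = "min")
      expect_true(all(rk[d$truth$sites] <= 5))
    }
  }
  expect_true(found)
})
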