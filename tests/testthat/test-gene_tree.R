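test_that("BIONJ recovers a 4-taxon additive tree with exact branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- stats::as.dist(ape::cophenetic.phylo(tr))
  est <- build_bionj(d)
  expect_equal(ape::Ntip(est), 4L)
  # AB|CD split present
  splits <- ape::prop.part(ape::unroot(est))
  expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # patristic distances reproduce the additive input exactly
  dd <- ape::cophenetic.phylo(est)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  expect_equal(dd, ape::cophenetic.phylo(tr)[rownames(dd), colnames(dd)],
               tolerance = 1e-10)
  expect_error(build_bionj(stats::as.dist(matrix(0, 2, 2))), "3 taxa")
})

test_that("BIONJ is invariant to taxon input order", {
  set.seed(11)
  tr <- random_additive_tree(7)
  D <- ape::cophenetic.phylo(tr)
  t1 <- build_bionj(stats::as.dist(D))
  perm <- sample(rownames(D))
  t2 <- build_bionj(stats::as.dist(D[perm, perm]))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("midpoint rooting splits a balanced quartet and is idempotent", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rt <- root_tree(ape::unroot(tr))
  expect_true(ape::is.rooted(rt))
  kids <- phangorn::Descendants(rt, ape::Ntip(rt) + 1L, type = "children")
  tipsets <- lapply(phangorn::Descendants(rt, kids, type = "tips"),
                    function(i) sort(rt$tip.label[i]))
  expect_true(setequal(tipsets, list(c("A", "B"), c("C", "D"))))
  rt2 <- root_tree(rt)
  expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(rt2)), 0, ignore_attr = TRUE)

  # caterpillar with one dominant terminal branch: root bisects its path
  cat_tr <- ape::read.tree(text = "(((A:0.1,B:0.1):0.1,C:0.1):0.1,D:10);")
  rcat <- root_tree(ape::unroot(cat_tr))
  kids <- phangorn::Descendants(rcat, ape::Ntip(rcat) + 1L, type = "children")
  tipsets <- lapply(phangorn::Descendants(rcat, kids, type = "tips"),
                    function(i) sort(rcat$tip.label[i]))
  expect_true(list("D") %in% tipsets)
})

test_that("newick round-trip preserves topology and branch lengths", {
  set.seed(5)
  tr <- random_additive_tree(8)
  txt <- ape::write.tree(tr)
  tr2 <- ape::read.tree(text = txt)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length), tolerance = 1e-9)
})

test_that("testable-node enumeration enforces clade and outgroup minima", {
  # 9 leaves: (4,4) under one child of the root, 1 outgroup leaf
  tr <- ape::read.tree(text = paste0(
    "(((a1:1,(a2:1,(a3:1,a4:1):1):1):1,(b1:1,(b2:1,(b3:1,b4:1):1):1):1):1,o1:1);"))
  parts <- enumerate_testable_nodes(tr)
  expect_length(parts, 1L)
  expect_setequal(parts[[1]]$clade_a, c("a1", "a2", "a3", "a4"))
  expect_setequal(parts[[1]]$clade_b, c("b1", "b2", "b3", "b4"))
  expect_setequal(parts[[1]]$outgroup, "o1")

  # balanced 8-leaf tree: the only (4,4) node is the root -> empty outgroup
  bal8 <- ape::read.tree(text = paste0(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);"))
  expect_length(enumerate_testable_nodes(bal8), 0L)

  # partitions always cover the leaf set exactly
  for (p in enumerate_testable_nodes(tr)) {
    expect_length(c(p$clade_a, p$clade_b, p$outgroup), ape::Ntip(tr))
    expect_length(intersect(p$clade_a, p$clade_b), 0L)
  }
})

test_that("enumeration agrees with a brute-force count on a balanced 16-leaf tree", {
  nest <- function(labels) {
    if (length(labels) == 1) return(labels)
    h <- length(labels) / 2
    sprintf("(%s:1,%s:1)", nest(labels[1:h]), nest(labels[-(1:h)]))
  }
  tr <- ape::read.tree(text = paste0(nest(paste0("t", 1:16)), ";"))
  parts <- enumerate_testable_nodes(tr)

  # brute force over all internal nodes
  ntip <- 16L
  desc <- phangorn::Descendants(tr, type = "tips")
  count <- 0L
  for (v in (ntip + 1L):(ntip + tr$Nnode)) {
    ch <- tr$edge[tr$edge[, 1] == v, 2]
    if (length(ch) != 2) next
    na <- length(desc[[ch[1]]]); nb <- length(desc[[ch[2]]])
    if (na >= 4 && nb >= 4 && (ntip - na - nb) >= 1) count <- count + 1L
  }
  expect_equal(length(parts), count)
  expect_equal(count, 2L)  # the two depth-1 (4,4) nodes; root excluded
})

test_that("BIONJ reproduces generating topologies from additive distances", {
  set.seed(42)
  for (i in 1:25) {
    tr <- random_additive_tree(sample(5:10, 1))
    est <- build_bionj(stats::as.dist(ape::cophenetic.phylo(tr)))
    expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})
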