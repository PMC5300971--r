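markers5 <- nk_panel()$nk_markers

test_that("percentile rescaling anchors p5 at -3 and p95 at +3 exactly", {
  withr::local_seed(14)
  ct <- data.frame(sample_id = "S1", cluster_id = 1:200,
                   matrix(rnorm(1000), 200, 5,
                          dimnames = list(NULL, markers5)),
                   event_count = 10, check.names = FALSE)
  rs <- rescale_centers(ct)
  for (m in markers5) {
    p <- quantile(ct[[m]], c(0.05, 0.95), names = FALSE, type = 7)
    expect_equal(unname(rescale_map(rs, m, p[1])), -3)
    expect_equal(unname(rescale_map(rs, m, p[2])), 3)
    # midpoint of the anchors maps to 0 by linearity
    expect_equal(unname(rescale_map(rs, m, mean(p))), 0)
    # stored matrix agrees with the stored map
    expect_equal(unname(rs$scaled[, m]), unname(rescale_map(rs, m, ct[[m]])))
  }
  # values beyond the anchors are not clipped
  expect_gt(max(rs$scaled), 3)
})

test_that("rescaling is idempotent on its own anchors and rejects flat markers", {
  withr::local_seed(15)
  ct <- data.frame(sample_id = "S1", cluster_id = 1:50,
                   matrix(runif(250), 50, 5, dimnames = list(NULL, markers5)),
                   event_count = 1, check.names = FALSE)
  rs <- rescale_centers(ct)
  ct2 <- data.frame(sample_id = "S1", cluster_id = 1:50, rs$scaled,
                    event_count = 1, check.names = FALSE)
  rs2 <- rescale_centers(ct2)
  for (m in markers5) {
    expect_equal(unname(rescale_map(rs2, m, rs2$anchors[m, "p5"])), -3)
    expect_equal(unname(rescale_map(rs2, m, rs2$anchors[m, "p95"])), 3)
  }
  ct$CD57 <- 1
  expect_error(rescale_centers(ct), "CD57")
})

test_that("average-linkage dendrogram matches hand-computed merges", {
  # 2 rows: single merge at their Euclidean distance
  x2 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  hc2 <- nk_hclust(x2)
  expect_equal(hc2$height, 5)

  # 4 points in 2 tight pairs: first two merges are the pairs, final height
  # is the mean of the 4 between-pair distances
  x4 <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  hc4 <- nk_hclust(x4)
  expect_equal(sort(hc4$height[1:2]), c(0.1, 0.1))
  between <- as.matrix(dist(x4))[1:2, 3:4]
  expect_equal(hc4$height[3], mean(between))
  # merge heights are monotone under average linkage
  expect_true(!is.unsorted(hc4$height))
})

test_that("tree cutting yields the requested number of groups", {
  withr::local_seed(16)
  x <- matrix(rnorm(60), 20, 3)
  hc <- nk_hclust(x)
  expect_equal(length(unique(cut_tree(hc, 1))), 1L)
  expect_equal(length(unique(cut_tree(hc, 20))), 20L)
  expect_equal(length(unique(cut_tree(hc, 7))), 7L)
  expect_error(cut_tree(hc, 0), "between")
  expect_error(cut_tree(hc, 21), "between")
})

test_that("metacluster partitions are invariant to input row order", {
  withr::local_seed(18)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, markers5))
  hc <- nk_hclust(x)
  perm <- sample(nrow(x))
  hc_p <- nk_hclust(x[perm, ])
  for (k in c(2, 5, 9)) {
    a <- cut_tree(hc, k)
    b <- cut_tree(hc_p, k)[order(perm)]
    expect_equal(ari(a, b), 1)
  }
})

test_that("rare metaclusters are flagged, not deleted", {
  # 19 metaclusters, 6 of them too small: 13 retained
  sizes <- c(rep(8, 13), rep(2, 6))
  # distinct high/low corner signatures so every marker carries signal
  sig <- as.matrix(expand.grid(rep(list(c(0, 4)), 5)))[1:19, ]
  colnames(sig) <- markers5
  ct <- toy_cluster_table(sizes, sig)
  rs <- rescale_centers(ct)
  labels <- cut_tree(nk_hclust(rs), 19)
  mc <- build_metaclusters(rs, labels)
  expect_equal(nrow(mc), 19L)
  mc1 <- filter_rare(mc, min_members = 1)
  expect_true(all(mc1$retained))
  mc3 <- filter_rare(mc, min_members = 3)
  expect_equal(sum(mc3$retained), 13L)
  expect_warning(filter_rare(mc, min_members = 100), "below min_members")
  # metaclusters partition the clusters; signatures are member means
  mem <- attr(mc, "membership")
  expect_equal(sort(unique(mem$metacluster_id)), sort(mc$metacluster_id))
  one <- mc$metacluster_id[1]
  expect_equal(unname(as.matrix(mc[1, markers5])[1, ]),
               unname(colMeans(rs$scaled[mem$metacluster_id == one, ,
                                         drop = FALSE])))
})

test_that("annotation rules name the canonical signatures", {
  sig <- function(cd56, cd16, nkg2a, nkg2c, cd57) {
    stats::setNames(c(cd56, cd16, nkg2a, nkg2c, cd57), markers5)
  }
  expect_equal(annotate_signature(sig(2.5, -2, 2, -1, -1)), "CD56bright")
  expect_equal(annotate_signature(sig(0.5, 2, -1, -1.5, -2)),
               "CD56dim NKG2A-NKG2C-CD57-")
  expect_equal(annotate_signature(sig(0, 0, 0, 0, 0)), "unclassified")
  expect_equal(annotate_signature(sig(0.7, 2.4, 2.1, -1.2, -1.4)),
               "CD56dim NKG2A+"
  )
  expect_equal(annotate_signature(sig(0.7, 2.4, -1.6, 2.2, 1.9)),
               "CD56dim NKG2C+CD57+")
  expect_equal(annotate_signature(sig(-2.5, 2.4, -1.6, -1.1, -1.4)),
               "CD56neg CD16+")
})

test_that("annotated metaclusters recover the generating phenotypes", {
  # build a cluster table directly from jittered phenotype means
  phen <- build_default_phenotypes()
  mu <- phenotype_means(phen)
  sizes <- rep(4, 13)
  ct <- toy_cluster_table(sizes, mu, jitter = 0.08, seed = 23)
  rs <- rescale_centers(ct)
  labels <- cut_tree(nk_hclust(rs), 13)
  mc <- annotate(filter_rare(build_metaclusters(rs, labels), 1))
  truth <- rep(rownames(mu), times = sizes)
  mem <- attr(mc, "membership")
  named <- stats::setNames(mc$population, mc$metacluster_id)
  got <- unname(named[as.character(mem$metacluster_id)])
  expect_gte(mean(got == truth), 0.9)
})

test_that("dendrograms export as parseable Newick", {
  withr::local_seed(20)
  x <- matrix(rnorm(40), 8, 5)
  rownames(x) <- paste0("c", 1:8)
  hc <- nk_hclust(x)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_equal(ape::Ntip(tree), 8L)
})

test_that("MeV-style export preserves the rescaled values", {
  withr::local_seed(24)
  ct <- data.frame(sample_id = "S1", cluster_id = 1:30,
                   matrix(rnorm(150), 30, 5, dimnames = list(NULL, markers5)),
                   event_count = 5, check.names = FALSE)
  rs <- rescale_centers(ct)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mev_table(rs, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, markers5]), rs$scaled, ignore_attr = TRUE,
               tolerance = 1e-12)
})
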