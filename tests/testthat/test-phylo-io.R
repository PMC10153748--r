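test_that("Newick parsing populates the tree and round-trips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  rt <- read_newick(write_newick(tr))
  expect_equal(ape::Ntip(rt), 3)
  expect_true(ape::all.equal.phylo(tr, rt, use.edge.length = TRUE))

  # generated 100-tip tree: topology identical, lengths within 1e-12
  big <- simulate_yule_tree(100, seed = 7)
  big2 <- read_newick(write_newick(big))
  expect_true(ape::all.equal.phylo(big, big2, use.edge.length = TRUE,
                                   tolerance = 1e-12))
})

test_that("invalid trees are rejected with informative errors", {
  expect_error(read_newick("((A:1,B:1):1,C:2"), "parsed|malformed")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate.*A")
  expect_error(read_newick("((A:1,B:1),C:2);"), "length")
  expect_error(read_newick("((A:1,B:-1):1,C:2);"), "length")
})

test_that("ultrametricity check reports the max tip-depth deviation", {
  ok <- check_ultrametric(read_newick("((A:1,B:1):1,C:2);"))
  expect_true(ok$ultrametric)
  expect_equal(ok$deviation, 0)

  bad <- check_ultrametric(read_newick("((A:1,B:2):1,C:2);"))
  expect_false(bad$ultrametric)
  expect_equal(bad$deviation, 1)

  # jittered tip edges within tolerance
  set.seed(11)
  tr <- simulate_yule_tree(30, seed = 11)
  term <- which(tr$edge[, 2] <= ape::Ntip(tr))
  tr$edge.length[term] <- tr$edge.length[term] +
    runif(length(term), -1e-9, 1e-9)
  expect_true(check_ultrametric(tr, tol = 1e-6)$ultrametric)
})

test_that("mean-edge consensus averages matched splits", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  same <- mean_edge_consensus(list(tr, tr))
  expect_true(ape::all.equal.phylo(tr, same, use.edge.length = TRUE))

  tr2 <- tr
  tr2$edge.length <- c(1, 1, 2, 2)[match(paste(tr2$edge[, 1], tr2$edge[, 2]),
                                         paste(tr$edge[, 1], tr$edge[, 2]))]
  # one edge at 1.0 in tr and 2.0 in tr2 must average to 1.5
  cons <- mean_edge_consensus(list(tr, tr2))
  expect_equal(cons$edge.length, (tr$edge.length + tr2$edge.length) / 2)

  # 10 jittered copies of a 20-tip tree vs brute-force averaging
  base <- simulate_yule_tree(20, seed = 3)
  set.seed(30)
  copies <- lapply(1:10, function(i) {
    tc <- base
    tc$edge.length <- tc$edge.length * runif(length(tc$edge.length), 0.9, 1.1)
    tc
  })
  cons <- mean_edge_consensus(copies)
  brute <- Reduce(`+`, lapply(copies, `[[`, "edge.length")) / 10
  expect_lt(max(abs(cons$edge.length - brute)), 1e-12)

  # cross-check against the established consensus implementation
  pc <- phytools::consensus.edges(copies, method = "mean.edge")
  key <- function(t) {
    nt <- ape::node.depth.edgelength(t)
    round(sort(nt[t$edge[, 2]]), 10)
  }
  expect_equal(key(cons), key(pc), tolerance = 1e-8)
})

test_that("consensus is order-invariant and rejects topology conflicts", {
  base <- simulate_yule_tree(12, seed = 5)
  set.seed(50)
  copies <- lapply(1:5, function(i) {
    tc <- base
    tc$edge.length <- tc$edge.length * runif(length(tc$edge.length), 0.8, 1.2)
    tc
  })
  a <- mean_edge_consensus(copies)
  b <- mean_edge_consensus(rev(copies))
  expect_equal(a$edge.length, b$edge.length)

  other <- read_newick("((A:1,C:1):1,B:2);")
  expect_error(mean_edge_consensus(list(read_newick("((A:1,B:1):1,C:2);"), other)),
               "topology mismatch.*A")
})

test_that("trait preparation averages, filters, logs and ln-transforms", {
  tr <- read_newick("((Sp_one:1,Sp_two:1):1,Sp_three:2);")
  rec <- data.frame(
    species = c("Sp one", "Sp one", "Sp two", "Sp three", "Sp three", "Sp three"),
    genome_size_pg = c(14, 16, 20, 14, 16, 18),
    svl_mm = c(60, 60, 30, 80, 80, 80),
    study_id = c("S2", "S3", "S2", "S1", "S2", "S3"))

  out <- prepare_traits(rec, tr)
  expect_equal(unname(out$x["Sp_one"]), log(15))
  # SVL below the 35 mm cutoff is excluded with the rule logged
  expect_false("Sp_two" %in% names(out$x))
  expect_match(out$exclusions$rule[out$exclusions$species == "Sp_two"], "SVL<35")

  # dropping a study changes the mean: {14(S1),16,18} minus S1 -> mean 17
  out2 <- prepare_traits(rec, tr, drop_study_ids = "S1")
  expect_equal(unname(out2$x["Sp_three"]), log(17))

  # retained + excluded = distinct species intersecting the tree
  expect_equal(length(out$x) + nrow(out$exclusions), 3L)

  # a tree tip with no record at all is a hard error
  rec_missing <- rec[rec$species != "Sp three", ]
  expect_error(prepare_traits(rec_missing, tr), "Sp_three")
})

test_that("pg-to-Mb conversion uses 978 Mb per pg", {
  expect_equal(pg_to_mb(1), 978)
  expect_equal(pg_to_mb(0), 0)
  expect_equal(pg_to_mb(22), 21516)
  expect_error(pg_to_mb(-1), "negative")
})
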