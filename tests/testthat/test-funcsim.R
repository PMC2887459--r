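toy_annot <- function(sets, parents = list()) {
  annotation_data(parents = parents, annotations = sets,
                  terms = sort(unique(c(unlist(sets), names(parents),
                                        unlist(parents)))))
}

test_that("SIC weighting is zero for universal terms and monotone in rarity", {
  sets <- c(lapply(1:10, function(i) c("root", paste0("t", i))),
            list(p_extra = c("root", "t1")))
  names(sets) <- c(paste0("p", 1:10), "p_extra")
  sic <- term_sic(toy_annot(sets))
  expect_equal(sic[["root"]], 0)
  expect_gt(sic[["t2"]], sic[["t1"]])   # t1 annotates 2 proteins, t2 one

  # |P| = 100, |P_t| = 10: direct evaluation of the normalised -log frequency
  sets2 <- stats::setNames(lapply(1:100, function(i) {
    if (i <= 10) c("root", "t") else "root"
  }), sprintf("q%03d", 1:100))
  sic2 <- term_sic(toy_annot(sets2))
  expect_equal(sic2[["t"]], -log(10 / 100) / log(100))
  expect_gt(sic2[["t"]], 0)
})

test_that("terms annotating no protein are excluded with a warning", {
  ad <- annotation_data(parents = list(b = "a", zzz = "a"),
                        annotations = list(p1 = "b", p2 = "b"))
  expect_warning(sic <- term_sic(ad), "exclude")
  expect_false("zzz" %in% names(sic))
})

test_that("functional similarity reproduces hand-computed ratios", {
  ad <- toy_annot(list(pa = c("r", "x"), pb = c("r", "x", "y"),
                       pc = c("r", "z"), pd = c("r", "x")))
  sic <- c(r = 0, x = 1, y = 2, z = 3)
  expect_equal(functional_similarity("pa", "pb", ad, sic), 1 / 3)
  expect_equal(functional_similarity("pa", "pd", ad, sic), 1)
  expect_equal(functional_similarity("pa", "pc", ad, sic), 0, tolerance = 1e-12)
  expect_true(is.na(functional_similarity("pa", "nope", ad, sic)))
})

test_that("functional similarity is reflexive, symmetric and root-stable", {
  sets <- list(p1 = c("r", "a"), p2 = c("r", "a", "b"), p3 = c("r", "c"))
  ad <- toy_annot(sets)
  sic <- term_sic(ad)
  for (p in names(sets)) {
    expect_equal(functional_similarity(p, p, ad, sic), 1)
  }
  expect_equal(functional_similarity("p1", "p2", ad, sic),
               functional_similarity("p2", "p1", ad, sic))
  # adding a universal term changes nothing: its SIC is 0
  sets_u <- lapply(sets, c, "universe")
  ad_u <- toy_annot(sets_u)
  sic_u <- term_sic(ad_u)
  expect_equal(functional_similarity("p1", "p2", ad_u, sic_u),
               functional_similarity("p1", "p2", ad, sic))
})

test_that("link similarity table joins betweenness, PCC and FS per edge", {
  g <- read_edge_list(withr::local_tempfile(lines = c("a b", "b c", "c a")))
  t <- seq_len(8)
  expr <- rbind(a = t + 0.1 * rnorm(8), b = -t)
  ad <- toy_annot(list(a = c("r", "x"), b = c("r", "x"), c = c("r", "y")))
  tab <- link_similarity_table(g, expr, ad)
  expect_equal(nrow(tab), 3)
  lb <- link_betweenness(g)
  expect_equal(tab$betweenness, lb$betweenness)
  # c has no expression row: PCC undefined, FS still computed
  ce <- tab[tab$from == "b" & tab$to == "c", ]
  expect_true(is.na(ce$pcc))
  expect_false(is.na(ce$functional_similarity))
})

test_that("pendant-edge records carry link betweenness N - 1", {
  s <- planted_modular_graph(c(6, 6), 0.8, 0.2, n_pendants = 3, seed = 21)
  g <- largest_connected_component(s$network)
  tab <- link_similarity_table(g)
  pend <- igraph::V(g)$name[igraph::degree(g) == 1]
  n <- igraph::vcount(g)
  for (p in pend) {
    expect_equal(tab$betweenness[tab$from == p | tab$to == p], n - 1)
  }
})

test_that("correlation of log betweenness behaves on constructed targets", {
  g <- largest_connected_component(random_graph(40, 0.1, seed = 31))
  tab <- link_similarity_table(g)
  tab$functional_similarity <- -log(tab$betweenness)
  out <- betweenness_similarity_correlation(tab, "functional_similarity", "pearson")
  expect_equal(out$r, -1)
  expect_lt(out$p_value, 1e-10)

  set.seed(1)
  tab$functional_similarity <- runif(nrow(tab))
  out2 <- betweenness_similarity_correlation(tab, "functional_similarity", "pearson")
  expect_lt(abs(out2$r), 0.4)   # small-n null: loose sanity bound

  tab$functional_similarity <- rank(-tab$betweenness) / nrow(tab)
  rp <- betweenness_similarity_correlation(tab, "functional_similarity", "pearson")$r
  rs <- betweenness_similarity_correlation(tab, "functional_similarity", "spearman")$r
  expect_equal(sign(rp), sign(rs))

  tab$functional_similarity <- rep(0.5, nrow(tab))
  expect_error(betweenness_similarity_correlation(tab, "functional_similarity"),
               "constant")
  expect_error(betweenness_similarity_correlation(tab[1:2, ], "pcc"), "3")
})

test_that("within-community links are more functionally similar than bridges", {
  s <- planted_modular_graph(c(15, 15, 15), 0.4, 0.04, seed = 41)
  ad <- simulate_ontology(3, 2, proteins = names(s$partition),
                          partition = s$partition, p_bias = 0.95, seed = 41)
  tab <- link_similarity_table(s$network, annot = ad)
  within <- s$partition[tab$from] == s$partition[tab$to]
  expect_gt(stats::median(tab$functional_similarity[within]),
            stats::median(tab$functional_similarity[!within]))
})
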