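de_stub <- function(features, lfc, call) {
  data.frame(feature = features, log2FC = lfc, call = call,
             stringsAsFactors = FALSE)
}

test_that("network edges carry regulation signs from direction comparison", {
  dem <- de_stub(c("miR-up", "miR-dn"), c(2, -1.5), c("up", "down"))
  deg <- de_stub(c("t-up", "t-dn"), c(1.2, -1.1), c("up", "down"))
  links <- data.frame(
    mirna = c("miR-up", "miR-up", "miR-dn"),
    target = c("t-dn", "t-up", "t-dn"), stringsAsFactors = FALSE)
  net <- build_network(dem, deg, links)
  expect_equal(nrow(net), 3L)
  get_reg <- function(m, t) net$regulation[net$mirna == m & net$target == t]
  expect_equal(get_reg("miR-up", "t-dn"), "anti")      # up miRNA, down target
  expect_equal(get_reg("miR-up", "t-up"), "positive")  # both up
  expect_equal(get_reg("miR-dn", "t-dn"), "positive")  # both down
  tot <- network_totals(net)
  expect_equal(unname(tot["anti"] + tot["positive"]), unname(tot["total"]))
  # pairs not involving DE features on both sides are excluded
  none <- build_network(dem, de_stub("t-ns", 0.1, "ns"), links)
  expect_equal(nrow(none), 0L)
})

test_that("hypergeometric tail matches enumeration and degenerate cases", {
  # N=10, K=5, n=2, k=2 -> C(5,2)/C(10,2) = 10/45
  res <- hypergeom_enrich(c("g1", "g2"),
                          list(tA = paste0("g", 1:5)),
                          population = paste0("g", 1:10))
  expect_equal(res$pvalue, 10 / 45)
  # k = 0 -> tail at zero is 1
  res0 <- hypergeom_enrich(c("g9", "g10"), list(tA = paste0("g", 1:5)),
                           population = paste0("g", 1:10))
  expect_equal(res0$pvalue, 1)
  # sample = population -> k = K, p = 1 for every term
  resf <- hypergeom_enrich(paste0("g", 1:10),
                           list(tA = paste0("g", 1:5), tB = paste0("g", 4:8)),
                           population = paste0("g", 1:10))
  expect_true(all(resf$pvalue == 1))
  # enumeration oracle over random instances with N <= 12
  set.seed(8)
  for (i in 1:10) {
    N <- sample(5:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    pop <- paste0("g", seq_len(N))
    smp <- sample(pop, n)
    k <- sum(smp %in% pop[seq_len(K)])
    got <- hypergeom_enrich(smp, list(t = pop[seq_len(K)]),
                            population = pop)$pvalue
    expect_equal(got, oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
  expect_warning(
    hypergeom_enrich("g1", list(bad = "zz", ok = c("g1", "g2")),
                     population = paste0("g", 1:5)),
    "no population gene")
})

test_that("pathway table parsing is exact, idempotent and order-invariant", {
  f <- system.file("extdata", "terpenoid_targets.tsv", package = "eumir")
  parsed <- parse_pathway_table(f)
  expect_equal(parsed$n_targets, 22L)
  expect_equal(parsed$n_mirnas, 34L)
  # multi-miRNA rows expand to one pair each
  df <- data.frame(target_id = "t1", mirnas = "a; b", ann = "x",
                   stringsAsFactors = FALSE)
  p2 <- parse_pathway_table(df)
  expect_equal(p2$pairs,
               data.frame(mirna = c("a", "b"), target = "t1",
                          stringsAsFactors = FALSE))
  # order invariance and idempotence
  tab <- read_tsv(f)
  shuf <- tab[rev(seq_len(nrow(tab))), ]
  pr <- parse_pathway_table(shuf)
  expect_equal(pr$pairs, parsed$pairs)
  expect_equal(pr$n_targets, parsed$n_targets)
  bad <- tab
  bad[3, 2] <- " "
  expect_error(parse_pathway_table(bad), "row 3")
})

test_that("scatter points mirror edges and land in the right quadrants", {
  dem <- de_stub(c("m1", "m2"), c(2, 2), c("up", "up"))
  deg <- de_stub(c("t1", "t2"), c(-1.5, 1.2), c("down", "up"))
  links <- data.frame(mirna = c("m1", "m2"), target = c("t1", "t2"),
                      stringsAsFactors = FALSE)
  net <- build_network(dem, deg, links)
  sc <- correlation_scatter_data(dem, deg, net)
  expect_equal(nrow(sc), nrow(net))
  anti <- sc[sc$regulation == "anti", ]
  expect_true(all(sign(anti$x) != sign(anti$y))) # quadrant II or IV
  pos <- sc[sc$regulation == "positive", ]
  expect_true(all(sign(pos$x) == sign(pos$y)))   # quadrant I or III
})

test_that("headline totals are recomputed from their components", {
  fams <- read_tsv(system.file("extdata", "known_family_sizes.tsv",
                               package = "eumir"))
  sizes <- setNames(fams$members, fams$family)
  expect_equal(length(sizes), 16L)
  expect_equal(family_total(sizes), 59L)
  expect_equal(catalog_total(family_total(sizes), 9L, 153L), 221L)
  expect_equal(pair_total(208L, 571L), 779L)
})
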