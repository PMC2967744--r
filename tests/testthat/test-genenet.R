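test_that("pearson matches hand-evaluated cases and rejects bad input", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
})

test_that("anchor lists equal a brute-force correlation filter", {
  mod <- module_spec(sprintf("m%d", 1:5), noise_sd = 0.8)
  ds <- gen_expression_panel(1, 30, 50, modules = list(mod),
                             anchor_genes = "m1", seed = 31)[[1]]
  for (sgn in c("positive", "negative")) {
    al <- anchor_list(ds, "m1", threshold = 0.3, sign = sgn)
    rho_all <- apply(ds$values, 1, function(v) cor(v, ds$values["m1", ]))
    rho_all <- rho_all[names(rho_all) != "m1"]
    want <- if (sgn == "positive") names(rho_all)[rho_all >= 0.3]
    else names(rho_all)[rho_all <= -0.3]
    expect_setequal(al$members$gene, want)
    expect_equal(al$members$rho,
                 unname(rho_all[al$members$gene]))
  }
  # impossible threshold gives an empty list; absent anchor errors
  expect_equal(nrow(anchor_list(ds, "m1", threshold = 1.01)$members), 0)
  expect_error(anchor_list(ds, "nope"), "not present")
})

test_that("zero-noise module genes all enter the anchor list", {
  mod <- module_spec(c("gA", "gB", "gC", "gD"), loading_range = c(1, 1),
                     noise_sd = 1e-9)
  ds <- gen_expression_panel(1, 12, 30, modules = list(mod), seed = 7)[[1]]
  al <- anchor_list(ds, "gA", threshold = 0.4, sign = "positive")
  expect_true(all(c("gB", "gC", "gD") %in% al$members$gene))
})

test_that("overlap test matches exhaustive enumeration on small universes", {
  # (4, 3) lists with overlap 2 in a universe of 10
  p_pkg <- overlap_p(4, 3, 2, 10)
  expect_equal(p_pkg, oracle_overlap_p(4, 3, 2, 10))
  # battery over all feasible configurations in a universe of up to 12
  for (universe in c(8, 12)) for (sa in c(2, 5)) for (sb in c(3, 4)) {
    for (ov in 0:min(sa, sb)) {
      expect_equal(overlap_p(sa, sb, ov, universe),
                   oracle_overlap_p(sa, sb, ov, universe),
                   tolerance = 1e-12,
                   info = sprintf("u=%d a=%d b=%d ov=%d", universe, sa, sb, ov))
    }
  }
})

test_that("overlap p-value is non-increasing in the observed overlap", {
  ps <- vapply(0:20, function(ov) overlap_p(100, 20, ov, 1000), 0)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("overlap_test intersects gene sets and guards the universe", {
  res <- overlap_test(c("a", "b", "c"), c("b", "c", "d"), universe = 10)
  expect_equal(res$overlap, 2)
  expect_equal(res$overlap_genes, c("b", "c"))
  expect_equal(res$p_value, overlap_p(3, 3, 2, 10))
  expect_error(overlap_test(letters[1:5], letters[3:8], universe = 6),
               "universe")
})

test_that("co-expression graph equals an all-pairs brute-force filter", {
  mod <- module_spec(sprintf("m%d", 1:6), noise_sd = 1)
  ds <- gen_expression_panel(1, 20, 40, modules = list(mod), seed = 13)[[1]]
  g <- build_coexpr_graph(ds, threshold = 0.5)
  cm <- cor(t(ds$values))
  want <- which(abs(cm) >= 0.5 & upper.tri(cm), arr.ind = TRUE)
  have <- paste(g$edges$a, g$edges$b)
  brute <- apply(want, 1, function(ij) {
    p <- sort(rownames(cm)[ij]); paste(p[1], p[2])
  })
  expect_setequal(have, brute)
  # zero-noise 4-gene module forms a clique
  mod0 <- module_spec(c("zA", "zB", "zC", "zD"), loading_range = c(1, 1),
                      noise_sd = 1e-9)
  ds0 <- gen_expression_panel(1, 8, 20, modules = list(mod0), seed = 2)[[1]]
  g0 <- build_coexpr_graph(ds0, threshold = 0.75)
  in_clique <- g0$edges$a %in% mod0$member_genes &
    g0$edges$b %in% mod0$member_genes
  expect_equal(sum(in_clique), 6)
})

test_that("constant genes are dropped with a warning", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(c("g1", "g2", "g3", "flat"), sprintf("s%d", 1:10)))
  m["flat", ] <- 5
  ds <- expr_dataset(m, "t")
  expect_warning(g <- build_coexpr_graph(ds, threshold = 0.1), "constant")
  expect_false("flat" %in% unlist(g$edges[, c("a", "b")]))
})

test_that("summary graph keeps edges by dataset support with mean weight", {
  gs <- lapply(1:6, function(i) {
    pairs <- if (i <= 4) list(c("x", "y"), c("y", "z")) else list(c("y", "z"))
    g <- make_graph(c("x", "y", "z"), pairs, rho = 0.1 * i, support = 1L)
    g$dataset_id <- sprintf("d%d", i)
    g
  })
  sg4 <- summary_graph(gs, min_support = 4)
  xy <- sg4$edges[sg4$edges$a == "x" & sg4$edges$b == "y", ]
  expect_equal(xy$support, 4L)
  expect_equal(xy$rho, mean(0.1 * (1:4)))
  expect_setequal(xy$datasets[[1]], sprintf("d%d", 1:4))
  yz <- sg4$edges[sg4$edges$a == "y", ]
  expect_equal(sg4$edges[sg4$edges$a == "y" & sg4$edges$b == "z", ]$support, 6L)

  # min_support = 1 is the union; too-large support empties the graph
  expect_equal(nrow(summary_graph(gs, min_support = 1)$edges), 2)
  expect_equal(nrow(summary_graph(gs[1:4], min_support = 4)$edges), 2)
  expect_error(summary_graph(gs, min_support = 7), "fewer graphs")

  # monotone non-increasing edge count in min_support
  counts <- vapply(1:6, function(ms)
    nrow(summary_graph(gs, min_support = ms)$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("connectivity ratio follows its definition", {
  expect_equal(connectivity_ratio(3, 3), 1)
  expect_equal(connectivity_ratio(3, 2), 2 / 3)
  expect_equal(connectivity_ratio(6, 7), 7 / 15)
  expect_error(connectivity_ratio(3, 4), "maximum")
})

test_that("a clique among isolated vertices is mined as one module", {
  nodes <- c(sprintf("k%d", 1:5), sprintf("iso%02d", 1:10))
  g <- make_graph(nodes, clique_pairs(sprintf("k%d", 1:5)))
  mods <- mine_dense(g, min_r = 0.4, min_size = 3)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$genes, sprintf("k%d", 1:5))
  expect_equal(mods[[1]]$r, 1)
})

test_that("two cliques joined by a bridge split into two modules", {
  c1 <- sprintf("a%d", 1:4); c2 <- sprintf("b%d", 1:4)
  g <- make_graph(c(c1, c2),
                  c(clique_pairs(c1), clique_pairs(c2), list(c("a4", "b1"))))
  mods <- mine_dense(g, min_r = 0.4, min_size = 3)
  expect_equal(serialize_modules(mods),
               c(paste(c1, collapse = ","), paste(c2, collapse = ",")))
  expect_true(all(vapply(mods, `[[`, 0, "r") == 1))
})

test_that("mining matches the exhaustive-primitive oracle on a fixture battery", {
  battery <- list(
    list(nodes = sprintf("v%02d", 1:5),
         pairs = clique_pairs(sprintf("v%02d", 1:5))),
    list(nodes = sprintf("v%02d", 1:8),
         pairs = c(clique_pairs(sprintf("v%02d", 1:4)),
                   clique_pairs(sprintf("v%02d", 5:8)),
                   list(c("v04", "v05")))),
    list(nodes = sprintf("v%02d", 1:6),
         pairs = c(clique_pairs(sprintf("v%02d", 1:5)),
                   list(c("v05", "v06")))),          # clique + pendant
    list(nodes = sprintf("v%02d", 1:7),
         pairs = path_pairs(sprintf("v%02d", 1:7))), # path: nothing dense
    list(nodes = sprintf("v%02d", 1:6),
         pairs = lapply(2:6, function(i) c("v01", sprintf("v%02d", i)))),
    list(nodes = sprintf("v%02d", 1:10),
         pairs = random_pairs(sprintf("v%02d", 1:10), 0.45, seed = 101)),
    list(nodes = sprintf("v%02d", 1:12),
         pairs = random_pairs(sprintf("v%02d", 1:12), 0.35, seed = 202)),
    list(nodes = sprintf("v%02d", 1:12),
         pairs = random_pairs(sprintf("v%02d", 1:12), 0.6, seed = 303)))
  for (min_r in c(0.4, 0.6)) for (fx in battery) {
    g <- make_graph(fx$nodes, fx$pairs)
    mods <- mine_dense(g, min_r = min_r, min_size = 3)
    oracle <- oracle_dense(fx$nodes, g$edges, min_r = min_r, min_size = 3)
    expect_equal(serialize_modules(mods),
                 sort(vapply(oracle, paste, "", collapse = ",")),
                 info = sprintf("battery graph n=%d min_r=%.1f",
                                length(fx$nodes), min_r))
    # every module qualifies, verified by exhaustive subset enumeration
    qual <- oracle_qualifying_subsets(fx$nodes, g$edges, min_r, 3)
    qual_keys <- vapply(qual, paste, "", collapse = ",")
    for (m in mods)
      expect_true(paste(m$genes, collapse = ",") %in% qual_keys)
  }
})

test_that("mined module statistics satisfy r > min_r by recount", {
  g <- make_graph(sprintf("v%02d", 1:12),
                  random_pairs(sprintf("v%02d", 1:12), 0.5, seed = 77))
  mods <- mine_dense(g, min_r = 0.4)
  for (m in mods) {
    expect_equal(m$r, connectivity_ratio(m$n, m$L))
    expect_gt(m$r, 0.4)
    expect_true(all(m$edges$a %in% m$genes & m$edges$b %in% m$genes))
  }
  expect_length(mine_dense(make_graph(character(), list())), 0)
})

test_that("coherence is the mean pairwise Jaccard of edge support profiles", {
  c1 <- c("x1", "x2", "x3")
  same <- make_graph(c1, clique_pairs(c1),
                     datasets = list(c("d1", "d2", "d3", "d4")))
  m_same <- mine_dense(same, min_r = 0.4)
  expect_equal(coherence_filter(m_same, 0)[[1]]$coherence, 1)

  # five edges with varying support: coherence equals the hand-computed mean
  nodes <- c("y1", "y2", "y3", "y4")
  sets <- list(c("d1", "d2"), c("d1", "d3"), c("d2", "d3"),
               c("d1", "d2"), c("d4", "d5"))
  g <- make_graph(nodes, c(clique_pairs(c("y1", "y2", "y3")),
                           list(c("y1", "y4"), c("y2", "y4"))))
  g$edges$datasets <- I(sets)
  mods <- mine_dense(g, min_r = 0.4)
  expect_length(mods, 1)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  # recover set order as stored on the mined module's edges
  esets <- mods[[1]]$edges$datasets
  pairs <- utils::combn(length(esets), 2)
  want <- mean(apply(pairs, 2, function(p) jac(esets[[p[1]]], esets[[p[2]]])))
  expect_equal(coherence_filter(mods, 0)[[1]]$coherence, want)
  # disjoint support on a two-edge module gives coherence 0
  g2 <- make_graph(c("z1", "z2", "z3"),
                   list(c("z1", "z2"), c("z2", "z3"), c("z1", "z3")))
  g2$edges$datasets <- I(list(c("d1"), c("d2"), c("d1")))
  m2 <- coherence_filter(mine_dense(g2, min_r = 0.4), 0)
  expect_equal(m2[[1]]$coherence, mean(c(0, 1, 0)))
  # filter removes incoherent modules
  expect_length(coherence_filter(mine_dense(g2, min_r = 0.4), 0.5), 0)
})

test_that("differential expression flags planted effects and controls type I", {
  members <- sprintf("m%d", 1:5)
  hit <- vapply(1:20, function(s) {
    ds <- gen_expression_panel(
      1, 20, 100,
      modules = list(module_spec(members, effect_size = 1.5, noise_sd = 0.5)),
      seed = s)[[1]]
    de <- differential_expression(ds, members)
    mean(members %in% de$significant_set)
  }, 0)
  expect_gte(mean(hit), 0.95)

  # under the null the significant fraction stays near alpha
  null_frac <- vapply(1:10, function(s) {
    ds <- gen_expression_panel(1, 50, 60, seed = 100 + s)[[1]]
    de <- differential_expression(ds)
    length(de$significant_set) / nrow(ds$values)
  }, 0)
  expect_lt(abs(mean(null_frac) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))

  ds <- gen_expression_panel(1, 10, 10, seed = 1)[[1]]
  expect_error(differential_expression(ds, "absent_gene"), "not in dataset")
  ds$labels[] <- c(0L, rep(1L, 9))
  expect_error(differential_expression(ds), ">= 2 samples")
})

test_that("holdout evaluation separates planted classes and is honest on noise", {
  members <- sprintf("m%d", 1:5)
  ds <- gen_expression_panel(
    1, 20, 100,
    modules = list(module_spec(members, effect_size = 5, noise_sd = 0.1)),
    seed = 41)[[1]]
  rep_sep <- holdout_eval(ds, members, n_repeats = 10, seed = 1)
  expect_equal(rep_sep$accuracy, 1)

  # labels independent of expression: accuracy near the majority rate
  ds0 <- gen_expression_panel(1, 20, 100, seed = 42)[[1]]
  rep_null <- holdout_eval(ds0, rownames(ds0$values)[1:10],
                           n_repeats = 40, seed = 2)
  maj <- max(mean(ds0$labels == 1), mean(ds0$labels == 0))
  se <- sd(rep_null$accuracies) / sqrt(rep_null$n_repeats)
  expect_lt(abs(rep_null$accuracy - maj), 3 * max(se, 0.05))

  # informative genes beat random gene panels of the same size
  ds1 <- gen_expression_panel(
    1, 40, 100,
    modules = list(module_spec(members, effect_size = 1.5, noise_sd = 0.5)),
    seed = 43)[[1]]
  acc_inf <- holdout_eval(ds1, members, n_repeats = 25, seed = 3)$accuracy
  set.seed(4)
  bg <- setdiff(rownames(ds1$values), members)
  acc_rand <- holdout_eval(ds1, sample(bg, 5), n_repeats = 25,
                           seed = 5)$accuracy
  expect_gt(acc_inf, acc_rand)
})
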