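test_that("hypergeometric tail matches enumeration and closed forms", {
  expect_equal(hypergeom_test(5, 5, 20, 20), 1.0)  # certain event
  expect_equal(hypergeom_test(0, 5, 4, 20), 1.0)   # upper tail includes 0
  # exhaustive enumeration over all 5-subsets of a 20-element population
  # with 4 marked elements
  subsets <- utils::combn(20, 5)
  hits <- colSums(subsets <= 4)
  expect_equal(hypergeom_test(3, 5, 4, 20), mean(hits >= 3))
  expect_error(hypergeom_test(6, 5, 4, 20), "inconsistent")
  expect_error(hypergeom_test(3, 5, 2, 20), "inconsistent")

  set.seed(12)
  for (i in 1:200) {
    N <- sample(20:500, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    krange <- max(0, n + K - N):min(n, K)
    k <- krange[sample.int(length(krange), 1)]
    expect_equal(hypergeom_test(k, n, K, N), hyper_tail_oracle(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("term-for-term: no refinement of the population gives p = 1", {
  g <- simulate_go(n_terms = 25, depth = 3, n_domains = 60, seed = 14)
  st <- study_set("everything", g$population)
  r <- term_for_term(st, g$population, g$dag, g$map)
  expect_true(all(r$p == 1.0))
  # zero-hit terms report p = 1 in the upper-tail convention
  st2 <- study_set("some", g$population[1:10])
  r2 <- term_for_term(st2, g$population, g$dag, g$map)
  expect_true(all(r2$p[r2$study_count == 0] == 1.0))
  expect_true(all(r2$study_count <= pmin(r2$study_size,
                                         r2$population_count)))
})

test_that("elim reduces an ancestor's significance once its child explains the signal", {
  # chain: root <- a <- b; 20-domain population: 10 on b, 5 on a only,
  # 5 on root only; the 5-domain study sits entirely on b
  dag <- go_dag(
    terms = data.frame(id = c("GO:1", "GO:2", "GO:3"),
                       name = c("root", "a", "b"),
                       namespace = "biological_process", obsolete = FALSE,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = c("GO:2", "GO:3"),
                       parent = c("GO:1", "GO:2"), rel = "is_a",
                       stringsAsFactors = FALSE))
  doms <- sprintf("d%02d", 1:20)
  map <- domain_go_map(c(
    stats::setNames(rep(list("GO:3"), 10), doms[1:10]),
    stats::setNames(rep(list("GO:2"), 5), doms[11:15]),
    stats::setNames(rep(list("GO:1"), 5), doms[16:20])), dag)
  st <- study_set("on b", doms[1:5])
  tft <- term_for_term(st, doms, dag, map)
  p_b <- choose(10, 5) / choose(20, 5)
  p_a <- (choose(15, 5)) / choose(20, 5)
  expect_equal(tft$p[tft$term == "GO:3"], p_b)
  expect_equal(tft$p[tft$term == "GO:2"], p_a)
  el <- topology_elim(st, doms, dag, map, sig_threshold = 0.05)
  expect_equal(el$p[el$term == "GO:3"], p_b)        # tested untouched
  expect_equal(el$p[el$term == "GO:2"], 1.0)        # signal stripped
  expect_equal(el$p[el$term == "GO:1"], 1.0)
  expect_gt(el$p[el$term == "GO:2"], tft$p[tft$term == "GO:2"])
})

test_that("elim with a vanishing threshold degenerates to term-for-term", {
  g <- simulate_go(n_terms = 50, depth = 4, n_domains = 300,
                   planted = c(0.5), seed = 21)
  tft <- term_for_term(g$study, g$population, g$dag, g$map)
  el <- topology_elim(g$study, g$population, g$dag, g$map,
                      sig_threshold = 1e-300)
  expect_identical(el$term, tft$term)
  expect_identical(el$p, tft$p)
  expect_identical(el$study_count, tft$study_count)
})

test_that("elim never makes an eliminated term's ancestors more significant", {
  for (seed in 1:5) {
    g <- simulate_go(n_terms = 40, depth = 4, n_domains = 400,
                     planted = c(0.5, 0.3), seed = seed)
    tft <- term_for_term(g$study, g$population, g$dag, g$map)
    el <- topology_elim(g$study, g$population, g$dag, g$map,
                        sig_threshold = 0.01)
    sig <- el$term[el$p < 0.01]
    anc <- unique(unlist(g$dag$ancestors[sig], use.names = FALSE))
    for (t in intersect(anc, el$term)) {
      expect_gte(el$p[el$term == t] + 1e-12, tft$p[tft$term == t])
      expect_lte(el$study_count[el$term == t],
                 tft$study_count[tft$term == t])
    }
  }
})

test_that("parent-child conditioning matches the hand-built 2x2 tables", {
  # diamond: T is_a P1, T is_a P2; P1, P2 is_a R
  dag <- go_dag(
    terms = data.frame(id = c("R", "P1", "P2", "T"),
                       name = c("R", "P1", "P2", "T"),
                       namespace = "biological_process", obsolete = FALSE,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = c("P1", "P2", "T", "T"),
                       parent = c("R", "R", "P1", "P2"), rel = "is_a",
                       stringsAsFactors = FALSE))
  doms <- sprintf("d%02d", 1:10)
  map <- domain_go_map(c(
    stats::setNames(rep(list("T"), 4), doms[1:4]),
    stats::setNames(rep(list("P1"), 2), doms[5:6]),
    stats::setNames(rep(list("P2"), 2), doms[7:8]),
    stats::setNames(rep(list("R"), 2), doms[9:10])), dag)
  st <- study_set("s", c("d01", "d02", "d05"))
  # union condition = P1 or P2 annotated = d1..d8: table k=2,n=3,K=4,N=8
  pu <- parent_child(st, doms, dag, map, "union")
  expect_equal(pu$p[pu$term == "T"],
               hyper_tail_oracle(2, 3, 4, 8))
  expect_equal(pu$p[pu$term == "T"], 0.5)
  # intersection condition = d1..d4, annotations saturate it: p = 1
  pi_ <- parent_child(st, doms, dag, map, "intersection")
  expect_equal(pi_$p[pi_$term == "T"], 1.0)
  # a term annotated identically to its single parent is no refinement
  dag2 <- go_dag(
    terms = data.frame(id = c("R", "A"), name = c("R", "A"),
                       namespace = "biological_process", obsolete = FALSE,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = "A", parent = "R", rel = "is_a",
                       stringsAsFactors = FALSE))
  map2 <- domain_go_map(stats::setNames(rep(list("A"), 6),
                                        paste0("x", 1:6)), dag2)
  st2 <- study_set("s", paste0("x", 1:2))
  r2 <- parent_child(st2, paste0("x", 1:6), dag2, map2, "union")
  expect_equal(r2$p[r2$term == "A"], 1.0)
  # single-parent terms: union and intersection agree everywhere
  g <- simulate_go(n_terms = 30, depth = 3, n_domains = 200,
                   planted = c(0.4), seed = 33)
  ru <- parent_child(g$study, g$population, g$dag, g$map, "union")
  ri <- parent_child(g$study, g$population, g$dag, g$map, "intersection")
  parents_of <- split(g$dag$edges$parent, g$dag$edges$child)
  singles <- names(parents_of)[lengths(parents_of) == 1L]
  for (t in intersect(singles, ru$term))
    expect_equal(ru$p[ru$term == t], ri$p[ri$term == t])
})

test_that("planted enrichment is recovered by all four methods", {
  hits <- c(tft = 0L, elim = 0L, pcu = 0L, pci = 0L)
  n_rep <- 10L
  for (seed in seq_len(n_rep)) {
    g <- simulate_go(n_terms = 60, depth = 4, n_domains = 1000,
                     planted = c(0.5), study_size = 30, seed = 100 + seed)
    planted <- names(g$truth$planted)
    top <- function(r) r$term[which.min(r$p)]
    if (top(term_for_term(g$study, g$population, g$dag, g$map)) == planted)
      hits["tft"] <- hits["tft"] + 1L
    if (top(topology_elim(g$study, g$population, g$dag, g$map)) == planted)
      hits["elim"] <- hits["elim"] + 1L
    if (top(parent_child(g$study, g$population, g$dag, g$map, "union")) ==
          planted)
      hits["pcu"] <- hits["pcu"] + 1L
    if (top(parent_child(g$study, g$population, g$dag, g$map,
                         "intersection")) == planted)
      hits["pci"] <- hits["pci"] + 1L
  }
  expect_true(all(hits >= n_rep - 1L))
})

test_that("multiple-testing adjustment follows the standard definitions", {
  g <- simulate_go(n_terms = 40, depth = 4, n_domains = 300,
                   planted = c(0.5), seed = 55)
  r <- term_for_term(g$study, g$population, g$dag, g$map)
  expect_identical(adjust(r, "none")$p_adjusted, r$p)
  rb <- adjust(r, "bonferroni")
  expect_equal(rb$p_adjusted, pmin(1, r$p * nrow(r)))
  # single test: bonferroni equals the raw p
  one <- r[1, , drop = FALSE]
  expect_equal(adjust(one, "bonferroni")$p_adjusted, one$p)
  rbh <- adjust(r, "bh")
  expect_equal(rbh$p_adjusted, bh_oracle(r$p))
  expect_error(adjust(r, "holm"), "arg")
})
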