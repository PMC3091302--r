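# a small fixed two-namespace ontology: bp root -> reg -> reg_sub,
#                                        bp root -> metab
#                                        mf root -> catal (part_of link too)
toy_dag <- function() {
  go_dag(
    terms = data.frame(
      id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
             "GO:0000010", "GO:0000011", "GO:0000099"),
      name = c("biological_process", "regulation", "regulation of X",
               "metabolism", "molecular_function", "catalysis",
               "obsolete term"),
      namespace = c(rep("biological_process", 4),
                    rep("molecular_function", 2), "biological_process"),
      obsolete = c(rep(FALSE, 6), TRUE),
      stringsAsFactors = FALSE),
    edges = data.frame(
      child = c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000011",
                "GO:0000003"),
      parent = c("GO:0000001", "GO:0000002", "GO:0000001", "GO:0000010",
                 "GO:0000004"),
      rel = c("is_a", "is_a", "is_a", "is_a", "part_of"),
      stringsAsFactors = FALSE))
}

test_that("OBO files parse and cycles are rejected at load", {
  dag <- toy_dag()
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, f)
  back <- read_obo(f)
  expect_setequal(back$terms$id, dag$terms$id)
  expect_equal(back$ancestors[["GO:0000003"]],
               dag$ancestors[["GO:0000003"]])
  expect_true(back$terms$obsolete[back$terms$id == "GO:0000099"])

  cyc <- c("format-version: 1.2", "", "[Term]", "id: GO:1", "name: a",
           "namespace: biological_process", "is_a: GO:2 ! b", "",
           "[Term]", "id: GO:2", "name: b",
           "namespace: biological_process", "is_a: GO:1 ! a")
  f2 <- withr::local_tempfile(fileext = ".obo")
  writeLines(cyc, f2)
  expect_error(read_obo(f2), "cycl.*GO:1.*GO:2")
})

test_that("pfam2go lines parse and unknown terms are dropped with warning", {
  dag <- toy_dag()
  f <- withr::local_tempfile()
  writeLines(c(
    "!date: 2009/10/01",
    "Pfam:PF00069 Pkinase > GO:catalysis ; GO:0000011",
    "Pfam:PF00069 Pkinase > GO:regulation of X ; GO:0000003",
    "Pfam:PF00071 Ras > GO:regulation ; GO:0000002"), f)
  map <- read_pfam2go(f, dag)
  expect_setequal(map[["PF00069"]], c("GO:0000003", "GO:0000011"))
  expect_equal(map[["PF00071"]], "GO:0000002")

  expect_warning(
    m2 <- domain_go_map(list(PF1 = c("GO:0000003", "GO:9999999",
                                     "GO:0000099")), dag),
    "dropped 2")
  expect_equal(m2[["PF1"]], "GO:0000003")
})

test_that("propagation is the transitive closure and is idempotent", {
  dag <- toy_dag()
  map <- domain_go_map(list(PF1 = "GO:0000003", PF2 = "GO:0000011"), dag)
  p <- propagate(dag, map)
  # GO:0000003 reaches regulation, metabolism (part_of) and the bp root
  expect_setequal(p[["PF1"]], c("GO:0000001", "GO:0000002", "GO:0000003",
                                "GO:0000004"))
  expect_setequal(p[["PF2"]], c("GO:0000010", "GO:0000011"))
  expect_identical(propagate(dag, p), p)

  set.seed(17)
  g <- simulate_go(n_terms = 40, depth = 4, n_domains = 30, seed = 2)
  R <- reachability_oracle(g$dag)
  p <- propagate(g$dag, g$map)
  for (d in names(g$map)) {
    direct <- g$map[[d]]
    expect_setequal(
      p[[d]],
      union(direct, colnames(R)[colSums(R[direct, , drop = FALSE]) > 0]))
  }
})

test_that("profiles count propagated annotations over namespace denominators", {
  dag <- toy_dag()
  map <- domain_go_map(list(PF1 = "GO:0000003", PF2 = "GO:0000002",
                            PF3 = "GO:0000011", PF4 = character(0)), dag)
  d <- domainome("G", c("PF1", "PF2", "PF3", "PF4"))
  pr <- profile(d, dag, map,
                c("GO:0000002", "GO:0000003", "GO:0000001", "GO:0000011"))
  # bp denominator: PF1, PF2 (PF3 is mf-only, PF4 unannotated)
  expect_equal(unname(pr$denominator["GO:0000002"]), 2)
  expect_equal(unname(pr$fraction["GO:0000002"]), 100)
  expect_equal(unname(pr$fraction["GO:0000003"]), 50)
  expect_equal(unname(pr$fraction["GO:0000001"]), 100)
  # mf denominator: PF3 alone
  expect_equal(unname(pr$fraction["GO:0000011"]), 100)
  # child fraction never exceeds the ancestor's
  expect_lte(pr$fraction["GO:0000003"], pr$fraction["GO:0000002"])
  expect_lte(pr$fraction["GO:0000002"], pr$fraction["GO:0000001"])

  none <- profile(domainome("E", "PFX"), dag, map, "GO:0000002")
  expect_true(is.na(none$fraction["GO:0000002"]))
  expect_error(profile(d, dag, map, "GO:7777777"), "unknown")
})

test_that("profiles are invariant to accession renaming", {
  set.seed(29)
  g <- simulate_go(n_terms = 30, depth = 3, n_domains = 40, seed = 3)
  doms <- names(g$map)
  terms <- g$dag$terms$id[2:6]
  p1 <- profile(domainome("G", doms), g$dag, g$map, terms)
  ren <- stats::setNames(unclass(g$map), paste0("NEW", seq_along(doms)))
  p2 <- profile(domainome("G", names(ren)), g$dag,
                structure(ren, class = "domain_go_map"), terms)
  expect_equal(p1$fraction, p2$fraction)
})

test_that("category flux counts gains/losses per branch along a lineage", {
  dag <- toy_dag()
  reg_pool <- paste0("R", 1:20)
  met_pool <- paste0("M", 1:20)
  map <- domain_go_map(
    c(stats::setNames(rep(list("GO:0000003"), 20), reg_pool),
      stats::setNames(rep(list("GO:0000004"), 20), met_pool)), dag)
  tr <- rooted_tree("(((A,B),C),D);")
  path <- c("N1", "N2", "N3")
  led <- structure(list(
    tree = tr,
    gains = list(N2 = reg_pool[1:6], N3 = reg_pool[7:10], A = character(0)),
    losses = list(N2 = met_pool[1:8], N3 = met_pool[9:14], A = character(0)),
    present = list(), root_gains = character(0)), class = "event_ledger")
  reg <- category_flux(led, path, dag, map, "GO:0000002")
  met <- category_flux(led, path, dag, map, "GO:0000004")
  expect_equal(reg$gains, c(N2 = 6L, N3 = 4L))
  expect_equal(reg$losses, c(N2 = 0L, N3 = 0L))
  expect_equal(met$losses, c(N2 = 8L, N3 = 6L))
  # planted bias: regulatory gains dominate, metabolic losses dominate
  expect_gt(reg$mean_gains, reg$mean_losses)
  expect_gt(met$mean_losses, met$mean_gains)
  # means times branch count equal column sums exactly
  expect_equal(reg$mean_gains * length(reg$branches), sum(reg$gains))
  expect_equal(met$mean_losses * length(met$branches), sum(met$losses))
  # single-branch path equals that branch's counts
  one <- category_flux(led, c("N1", "N2"), dag, map, "GO:0000002")
  expect_equal(one$mean_gains, 6)
  expect_error(category_flux(led, c("N1", "N3"), dag, map, "GO:0000002"),
               "not a connected chain")
})

test_that("profile coordinates extract the two named fractions", {
  dag <- toy_dag()
  map <- domain_go_map(list(PF1 = "GO:0000002", PF2 = "GO:0000011",
                            PF3 = c("GO:0000002", "GO:0000011")), dag)
  d <- domainome("G", c("PF1", "PF2", "PF3"))
  pr <- profile(d, dag, map, c("GO:0000002", "GO:0000011"))
  co <- profile_coordinates(list(pr), "GO:0000002", "GO:0000011")
  expect_equal(co$x, unname(pr$fraction["GO:0000002"]))
  expect_equal(co$y, unname(pr$fraction["GO:0000011"]))
  co2 <- profile_coordinates(list(pr, pr), "GO:0000002", "GO:0000011")
  expect_equal(co2$x[1], co2$x[2])
  pr2 <- profile(d, dag, map, "GO:0000002")
  expect_error(profile_coordinates(list(pr2), "GO:0000002", "GO:0000011"),
               "lacks term")
})

test_that("profile clustering merges identical genomes first, outliers last", {
  dag <- toy_dag()
  map <- domain_go_map(list(PF1 = "GO:0000002", PF2 = "GO:0000004",
                            PF3 = "GO:0000003"), dag)
  terms <- c("GO:0000002", "GO:0000003", "GO:0000004")
  same1 <- profile(domainome("A", c("PF1", "PF2")), dag, map, terms)
  same2 <- profile(domainome("B", c("PF1", "PF2")), dag, map, terms)
  near <- profile(domainome("D", "PF1"), dag, map, terms)
  outlier <- profile(domainome("C", "PF3"), dag, map, terms)
  ref <- rooted_tree("((A,B),(C,D));")
  cl <- cluster_profiles(list(same1, same2, near, outlier), ref)
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(cl$hclust$labels[cl$hclust$merge[1, ] * -1], c("A", "B"))
  # the outlier is the last to join
  expect_true(-match("C", cl$hclust$labels) %in%
                cl$hclust$merge[nrow(cl$hclust$merge), ])
  expect_gte(cl$congruence, 0)
  expect_lte(cl$congruence, 1)

  bad <- profile(domainome("E", "PF1"), dag, map, terms[1:2])
  expect_error(cluster_profiles(list(same1, same2, bad), ref),
               "term vector")
})
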