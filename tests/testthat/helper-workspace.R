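# Build a complete on-disk synthetic workspace (tree, per-genome hit
# tables, OBO ontology, external2go map, exclusion list, pipeline config)
# and return the config plus the generating truth.
make_workspace <- function(dir, seed, n_leaves = 6L, n_domains = 60L,
                           loss_prob = 0.1, n_decoys = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tr <- simulate_tree(n_leaves)
  sim <- simulate_domain_evolution(tr, n_domains, loss_prob = loss_prob,
                                   seed = seed + 1L)
  tree_path <- file.path(dir, "tree.nwk")
  write_newick(tr, tree_path)

  hits <- list()
  excl_accs <- character(0)
  for (i in seq_along(sim$domainomes)) {
    d <- sim$domainomes[[i]]
    ht <- simulate_hit_table(d, n_decoys = n_decoys,
                             seed = seed + 10L + i)
    p <- file.path(dir, paste0(d$label, "_hits.tsv"))
    write_hits_tsv(ht$hits, p)
    hits[[d$label]] <- p
    excl_accs <- union(excl_accs, ht$exclusion$accessions)
  }
  excl_path <- file.path(dir, "exclusions.txt")
  writeLines(c("# synthetic viral/transposon decoys", sort(excl_accs)),
             excl_path)

  g <- simulate_go(n_terms = 25, depth = 3, n_domains = 5,
                   study_size = 2L, seed = seed + 2L)
  universe <- colnames(sim$matrix)
  gomap <- random_annotation(g$dag, universe)
  obo_path <- file.path(dir, "ontology.obo")
  map_path <- file.path(dir, "pfam2go.txt")
  write_obo(g$dag, obo_path)
  write_pfam2go(gomap, g$dag, map_path)

  ids <- g$dag$terms$id
  layer1 <- ids[order(g$dag$depth[ids], ids)][-1L][1:2]  # two broad terms
  inner <- root_path(tr, leaf_labels(tr)[1L])
  flux_path <- inner[-length(inner)]           # root .. parent of leaf 1
  if (length(flux_path) < 2L) flux_path <- inner[1:2]
  cfg <- list(
    tree = tree_path, hits = hits, obo = obo_path, map = map_path,
    exclusions = excl_path,
    cutoff = list(mode = "GA"),
    enrich = list(study_node = flux_path[length(flux_path)],
                  study_set = "gained", method = "tft",
                  correction = "none"),
    axes = list(x = layer1[1L], y = layer1[2L]),
    categories = list(regulatory = layer1[1L],
                      metabolic = layer1[min(2L, length(layer1))]),
    flux_path = flux_path,
    out_dir = file.path(dir, "out"),
    seed = seed, log_level = "quiet")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  list(cfg = cfg, tree = tr, sim = sim, dag = g$dag, map = gomap)
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(unname(tools::md5sum(files)),
                  sub(paste0("^", dir, "/?"), "", files))
}
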