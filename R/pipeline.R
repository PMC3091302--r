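#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with the
#' keys below; unknown keys are rejected so typos fail fast.
#'
#' \describe{
#'   \item{tree}{Newick file path.}
#'   \item{hits}{named list: genome label -> hit-table path (minimal TSV
#'     dialect, or HMMER domtblout if the name ends in `.domtbl`).}
#'   \item{obo}{OBO ontology path.}
#'   \item{map}{pfam2go/external2go mapping path.}
#'   \item{exclusions}{optional exclusion-list path.}
#'   \item{cutoff}{list: `mode` (GA/NC/TC/EVALUE) and, for EVALUE,
#'     `evalue`.}
#'   \item{enrich}{list: `study_node`, `study_set` ("gained" or "lost"),
#'     `method` (tft/elim/pcu/pci), `threshold` (elim), `correction`
#'     (none/bonferroni/bh), `namespace`.}
#'   \item{axes}{list: `x`, `y` GO ids for profile coordinates.}
#'   \item{categories}{list: `regulatory`, `metabolic` GO ids for flux.}
#'   \item{flux_path}{character vector of node names, root-to-node.}
#'   \item{out_dir}{output directory (created).}
#'   \item{seed}{integer seed recorded in the manifest.}
#'   \item{log_level}{"quiet" or "info" (default).}
#' }
#'
#' @param cfg named list or YAML file path.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  known <- c("tree", "hits", "obo", "map", "exclusions", "cutoff",
             "enrich", "axes", "categories", "flux_path", "out_dir",
             "seed", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  required <- c("tree", "hits", "obo", "map", "cutoff", "enrich",
                "axes", "categories", "flux_path", "out_dir", "seed")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  if (is.null(names(cfg$hits)) || any(!nzchar(names(cfg$hits))))
    stop("cfg$hits must be a named list: genome label -> file")
  cfg$log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  for (f in c(cfg$tree, cfg$obo, cfg$map, cfg$exclusions,
              unlist(cfg$hits)))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(cfg, class = c("pipeline_config", "list"))
}

pl_log <- function(cfg, stage, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

pl_stage <- function(cfg, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  pl_log(cfg, stage, "done in %.2fs", proc.time()[["elapsed"]] - t0)
  out
}

#' Run the full ancestral-domainome pipeline
#'
#' filter -> matrix -> Dollo reconstruction -> functional profiles and
#' per-branch flux -> GO enrichment of a chosen branch's gained or lost
#' set, with all tables written under the configured output directory:
#' per-genome and per-node domain lists (`nodes/`), per-branch ledger
#' TSVs, annotated phyloXML, profile coordinates, flux table, enrichment
#' table, and a run manifest recording the package version, seed and a
#' hash over config and inputs. A rerun on identical inputs is
#' byte-identical.
#'
#' @param cfg a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @return Invisibly, a list with the in-memory `ledger`, `profiles`,
#'   `flux`, `enrichment`, and the output `paths`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out_dir, "nodes"), showWarnings = FALSE)

  tree <- pl_stage(cfg, "read_tree", read_newick(cfg$tree))
  dag <- pl_stage(cfg, "read_obo", read_obo(cfg$obo))
  gomap <- pl_stage(cfg, "read_map", read_pfam2go(cfg$map, dag))
  excl <- if (!is.null(cfg$exclusions))
    read_exclusion_list(cfg$exclusions) else exclusion_list()
  policy <- cutoff_policy(cfg$cutoff$mode,
                          evalue_threshold = cfg$cutoff$evalue)

  domainomes <- pl_stage(cfg, "filter", {
    lapply(names(cfg$hits), function(g) {
      path <- cfg$hits[[g]]
      hits <- if (grepl("\\.domtbl$", path)) read_domtbl(path)
              else read_hits_tsv(path)
      d <- build_domainome(hits, policy, excl, label = g)
      pl_log(cfg, "filter", "%s: %d hits -> %d domains", g, nrow(hits),
             length(d$domains))
      d
    })
  })
  mat <- pl_stage(cfg, "matrix", build_matrix(domainomes))
  ledger <- pl_stage(cfg, "reconstruct", reconstruct(tree, mat))

  pl_stage(cfg, "export_ledger", {
    write_matrix_tsv(mat, file.path(cfg$out_dir, "presence_matrix.tsv"))
    write_ledger_tsv(ledger, file.path(cfg$out_dir, "ledger"))
    for (n in names(ledger$present))
      writeLines(ledger$present[[n]],
                 file.path(cfg$out_dir, "nodes", paste0(n, ".txt")))
    write_phyloxml(tree, file.path(cfg$out_dir, "annotated_tree.xml"),
                   ledger = ledger, domain_lists = TRUE)
  })

  prof_terms <- sort(unique(c(cfg$axes$x, cfg$axes$y,
                              cfg$categories$regulatory,
                              cfg$categories$metabolic)))
  profiles <- pl_stage(cfg, "profiles", {
    anc <- lapply(names(ledger$present), function(n)
      domainome(n, ledger$present[[n]]))
    lapply(anc, profile, dag = dag, map = gomap, terms = prof_terms)
  })
  coords <- profile_coordinates(profiles, cfg$axes$x, cfg$axes$y)
  utils::write.table(coords, file.path(cfg$out_dir, "profile_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  flux <- pl_stage(cfg, "flux", {
    out <- lapply(c(regulatory = cfg$categories$regulatory,
                    metabolic = cfg$categories$metabolic),
                  function(cat) category_flux(ledger, cfg$flux_path,
                                              dag, gomap, cat))
    tb <- do.call(rbind, lapply(names(out), function(nm) data.frame(
      category = nm, term = out[[nm]]$category,
      branch = out[[nm]]$branches,
      gains = out[[nm]]$gains, losses = out[[nm]]$losses,
      stringsAsFactors = FALSE)))
    utils::write.table(tb, file.path(cfg$out_dir, "category_flux.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  enrichment <- pl_stage(cfg, "enrich", {
    node <- cfg$enrich$study_node
    root_name <- tree$labels[tree$root]
    doms <- if (identical(cfg$enrich$study_set, "lost"))
      ledger$losses[[node]]
    else if (node == root_name) ledger$root_gains
    else ledger$gains[[node]]
    study <- study_set(sprintf("%s at %s", cfg$enrich$study_set, node),
                       doms)
    population <- colnames(mat)
    ns <- if (is.null(cfg$enrich$namespace)) "biological_process"
          else cfg$enrich$namespace
    res <- switch(cfg$enrich$method,
      tft = term_for_term(study, population, dag, gomap, namespace = ns),
      elim = topology_elim(study, population, dag, gomap,
                           sig_threshold = cfg$enrich$threshold %||% 0.01,
                           namespace = ns),
      pcu = parent_child(study, population, dag, gomap, "union", ns),
      pci = parent_child(study, population, dag, gomap, "intersection", ns),
      stop("unknown enrichment method: ", cfg$enrich$method))
    res <- adjust(res, cfg$enrich$correction %||% "none")
    write_enrichment_tsv(res, file.path(cfg$out_dir, "enrichment.tsv"))
    res
  })

  manifest <- list(
    package = "domevol",
    version = as.character(utils::packageVersion("domevol")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    input_hash = unname(tools::md5sum(
      sort(c(cfg$tree, cfg$obo, cfg$map, cfg$exclusions,
             unlist(cfg$hits, use.names = FALSE))))))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(ledger = ledger, profiles = profiles, flux = flux,
                 enrichment = enrichment,
                 paths = list.files(cfg$out_dir, recursive = TRUE,
                                    full.names = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # canonical text form of the config; md5 over it
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}
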