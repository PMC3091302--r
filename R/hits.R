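#' Construct a table of domain hits
#'
#' A `domain_hits` object is a data frame with one row per scored match of a
#' domain model to a protein: protein id, version-stripped domain accession,
#' 1-based inclusive envelope coordinates, independent E-value, bit score,
#' and optional per-domain gathering (GA), noise (NC) and trusted (TC)
#' bit-score thresholds.
#'
#' @param protein_id character vector of protein identifiers.
#' @param domain_acc character vector of domain accessions; any trailing
#'   version suffix (`PF00069.21`) is stripped (`PF00069`).
#' @param env_start,env_end integer envelope coordinates, 1-based inclusive.
#' @param i_evalue nonnegative independent E-values.
#' @param bit_score bit scores.
#' @param ga,nc,tc optional per-domain (domain-level) threshold scores;
#'   `NA` where Pfam provides none.
#' @return A data frame of class `domain_hits`.
#' @export
domain_hits <- function(protein_id, domain_acc, env_start, env_end,
                        i_evalue, bit_score,
                        ga = NA_real_, nc = NA_real_, tc = NA_real_) {
  df <- data.frame(
    protein_id = as.character(protein_id),
    domain_acc = strip_acc_version(as.character(domain_acc)),
    env_start  = as.integer(env_start),
    env_end    = as.integer(env_end),
    i_evalue   = as.numeric(i_evalue),
    bit_score  = as.numeric(bit_score),
    ga = as.numeric(ga), nc = as.numeric(nc), tc = as.numeric(tc),
    stringsAsFactors = FALSE
  )
  validate_hits(df)
  class(df) <- c("domain_hits", "data.frame")
  df
}

strip_acc_version <- function(acc) sub("\\.\\d+$", "", acc)

validate_hits <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$env_start < 1L)) stop("env_start must be >= 1")
  if (any(df$env_end < df$env_start)) stop("env_end must be >= env_start")
  if (any(df$i_evalue < 0)) stop("i_evalue must be nonnegative")
  invisible(df)
}

#' Define a hit-significance cutoff policy
#'
#' Hits are judged either by a per-domain curated bit-score threshold
#' (Pfam gathering, noise, or trusted cutoffs, applied at the domain level)
#' or by a uniform independent E-value threshold.
#'
#' @param mode one of `"GA"`, `"NC"`, `"TC"`, `"EVALUE"`.
#' @param evalue_threshold positive E-value threshold, required (and only
#'   used) when `mode = "EVALUE"`; thresholds anywhere on and beyond the
#'   1e-4 .. 1e-18 grid are accepted.
#' @return An object of class `cutoff_policy`.
#' @export
cutoff_policy <- function(mode = c("GA", "NC", "TC", "EVALUE"),
                          evalue_threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "EVALUE") {
    if (is.null(evalue_threshold))
      stop("EVALUE mode requires evalue_threshold")
    evalue_threshold <- as.numeric(evalue_threshold)
    if (!is.finite(evalue_threshold) || evalue_threshold <= 0)
      stop("configuration error: evalue_threshold must be a positive real")
  } else if (!is.null(evalue_threshold)) {
    stop("evalue_threshold is only meaningful in EVALUE mode")
  }
  structure(list(mode = mode, evalue_threshold = evalue_threshold),
            class = "cutoff_policy")
}

#' Build an exclusion list of domain accessions
#'
#' Domains of obvious viral, phage, or transposon origin are removed from
#' repertoires by exact match on the version-stripped accession.
#'
#' @param accessions character vector of accessions to drop.
#' @param reason optional free-text reason per entry (recycled).
#' @return An object of class `exclusion_list`.
#' @export
exclusion_list <- function(accessions = character(), reason = "") {
  accessions <- strip_acc_version(as.character(accessions))
  structure(list(accessions = accessions,
                 reason = rep_len(as.character(reason),
                                  length(accessions))),
            class = "exclusion_list")
}

#' Filter hits by a cutoff policy
#'
#' GA/NC/TC modes keep a hit iff its bit score is at least the hit's
#' domain-level threshold of that kind; EVALUE mode keeps a hit iff its
#' independent E-value is at most the threshold. Input order is preserved.
#'
#' @param hits a `domain_hits` data frame.
#' @param policy a [cutoff_policy()].
#' @return The passing subset of `hits`, in input order.
#' @export
apply_cutoffs <- function(hits, policy) {
  stopifnot(inherits(policy, "cutoff_policy"))
  if (nrow(hits) == 0L) return(hits)
  if (policy$mode == "EVALUE") {
    keep <- hits$i_evalue <= policy$evalue_threshold
  } else {
    thr <- hits[[tolower(policy$mode)]]
    if (anyNA(thr)) {
      bad <- which(is.na(thr))[1L]
      stop(sprintf(
        "missing %s threshold for hit of domain %s on protein %s",
        policy$mode, hits$domain_acc[bad], hits$protein_id[bad]))
    }
    if (any(thr < 0)) stop("configuration error: negative threshold score")
    keep <- hits$bit_score >= thr
  }
  hits[keep, , drop = FALSE]
}

#' Remove hits whose domain is on an exclusion list
#'
#' @param hits a `domain_hits` data frame.
#' @param excl an [exclusion_list()]; empty lists are valid.
#' @return `hits` without rows matching an excluded accession, in order.
#' @export
remove_excluded <- function(hits, excl) {
  stopifnot(inherits(excl, "exclusion_list"))
  if (nrow(hits) == 0L || length(excl$accessions) == 0L) return(hits)
  hits[!(hits$domain_acc %in% excl$accessions), , drop = FALSE]
}

#' Resolve overlapping hits on one protein
#'
#' Of overlapping domain hits only the one with the lowest E-value is
#' retained. Candidates are ranked by (i_evalue ascending, bit_score
#' descending, domain_acc ascending, env_start ascending) and accepted
#' greedily iff they share no residue with an already-accepted hit; two
#' hits overlap iff their `[env_start, env_end]` intervals share at least
#' one position. The total tie-break key makes the result independent of
#' input order.
#'
#' @param hits a `domain_hits` data frame, all rows on the same protein.
#' @return The accepted, pairwise non-overlapping subset in rank order.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$protein_id)) != 1L)
    stop("resolve_overlaps expects hits on a single protein; group by protein_id first")
  ord <- order(hits$i_evalue, -hits$bit_score, hits$domain_acc, hits$env_start)
  hits <- hits[ord, , drop = FALSE]
  acc_s <- integer(0); acc_e <- integer(0)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$env_start[i]; e <- hits$env_end[i]
    if (!any(s <= acc_e & e >= acc_s)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Build a domain repertoire (domainome) from raw hits
#'
#' Runs the full preprocessing chain: cutoff filtering, exclusion-list
#' removal, then per-protein overlap resolution, and collects the set of
#' distinct surviving domain accessions. Copy number is discarded: the
#' repertoire is a set of domain types, not tokens.
#'
#' @param hits a `domain_hits` data frame covering one genome.
#' @param policy a [cutoff_policy()].
#' @param excl an [exclusion_list()]; defaults to empty.
#' @param label genome label for the resulting domainome.
#' @return A [domainome()].
#' @export
build_domainome <- function(hits, policy, excl = exclusion_list(),
                            label = "genome") {
  hits <- apply_cutoffs(hits, policy)
  hits <- remove_excluded(hits, excl)
  if (nrow(hits) > 0L) {
    parts <- split(seq_len(nrow(hits)), hits$protein_id)
    kept <- lapply(names(parts), function(p) {
      tryCatch(resolve_overlaps(hits[parts[[p]], , drop = FALSE]),
               error = function(e)
                 stop(sprintf("protein %s: %s", p, conditionMessage(e))))
    })
    hits <- do.call(rbind, kept)
  }
  domainome(label, unique(hits$domain_acc))
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Whitespace-delimited, `#`-comment format as written by
#' `hmmscan --domtblout`. Target name/accession are taken as the domain
#' (accession preferred when present, else the name), query name as the
#' protein; i-Evalue, score and envelope from/to columns are used.
#'
#' @param path file path.
#' @return A `domain_hits` data frame (GA/NC/TC are `NA`: domtblout does
#'   not carry Pfam threshold scores).
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(domain_hits(character(), character(), integer(), integer(),
                       numeric(), numeric()))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) < 23L)
  if (length(bad))
    stop(sprintf("malformed domtblout record at data line %d of %s",
                 bad[1L], path))
  f <- function(i) vapply(fields, `[[`, "", i)
  t_name <- f(1); t_acc <- f(2); q_name <- f(4)
  acc <- ifelse(t_acc == "-", t_name, t_acc)
  domain_hits(protein_id = q_name, domain_acc = acc,
              env_start = as.integer(f(20)), env_end = as.integer(f(21)),
              i_evalue = as.numeric(f(13)), bit_score = as.numeric(f(14)))
}

#' Read the minimal 7-column TSV hit dialect
#'
#' Columns: protein_id, domain_acc, env_start, env_end, i_evalue,
#' bit_score, ga_dom (domain-level gathering threshold; `NA` allowed).
#' Lines starting with `#` are comments; a header row is detected and
#' skipped.
#'
#' @param path file path.
#' @return A `domain_hits` data frame.
#' @export
read_hits_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^protein_id\t", lines[1L]))
    lines <- lines[-1L]
  if (length(lines) == 0L)
    return(domain_hits(character(), character(), integer(), integer(),
                       numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 7L)
  if (length(bad))
    stop(sprintf("malformed hit record at line %d of %s", bad[1L], path))
  f <- function(i) vapply(fields, `[[`, "", i)
  domain_hits(protein_id = f(1), domain_acc = f(2),
              env_start = as.integer(f(3)), env_end = as.integer(f(4)),
              i_evalue = as.numeric(f(5)), bit_score = as.numeric(f(6)),
              ga = suppressWarnings(as.numeric(f(7))))
}

#' Write hits in the minimal TSV dialect
#' @param hits a `domain_hits` data frame.
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tdomain_acc\tenv_start\tenv_end\ti_evalue\tbit_score\tga_dom",
             con)
  if (nrow(hits))
    writeLines(sprintf("%s\t%s\t%d\t%d\t%.6g\t%.4f\t%s",
                       hits$protein_id, hits$domain_acc,
                       hits$env_start, hits$env_end,
                       hits$i_evalue, hits$bit_score,
                       ifelse(is.na(hits$ga), "NA", sprintf("%.2f", hits$ga))),
               con)
  invisible(path)
}

#' Read an exclusion list file
#'
#' One accession per line, optional tab-separated reason, `#` comments.
#'
#' @param path file path.
#' @return An [exclusion_list()].
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(exclusion_list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  exclusion_list(
    accessions = vapply(parts, `[[`, "", 1L),
    reason = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  )
}
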