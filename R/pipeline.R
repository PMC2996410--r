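#' Pipeline configuration
#'
#' A flat key-value configuration covering every stage: simulation
#' (clade structure, gain/loss rates, sequence divergence), homology
#' search thresholds, reference assignment, clustering and output. A
#' fully resolved copy is written alongside every run. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults (see `default_config()`).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @export
default_config <- function() {
  list(
    n_clades = 4L, leaves_per_clade = 4L, n_families = 300L,
    gain_rate = 0.3, loss_rate = 0.3, root_presence_prob = NA_real_,
    within_clade_depth = 0.5, between_clade_depth = 3.0,
    sub_rate = 0.1, root_len_min = 80L, root_len_max = 150L,
    seed = 1L,
    run_bbh = TRUE,
    min_alignment_columns = 70, min_percent_identity = 20,
    evalue_threshold = 1e-3,
    categories = "J,A,K,L,B,F",
    gap_open = 11L, gap_extend = 1L,
    lambda_stat = 0.267, k_stat = 0.041,
    linkage = "complete",
    newick_precision = 6L,
    simulate = TRUE,
    outdir = "phyletic_run"
  )
}

validate_config <- function(cfg) {
  num <- function(k) {
    v <- cfg[[k]]
    cfg[[k]] <<- if (is.character(v) && toupper(trimws(v)) == "NA")
      NA_real_ else as.numeric(v)
  }
  int <- function(k) { cfg[[k]] <<- as.integer(cfg[[k]]) }
  lgl <- function(k) {
    v <- cfg[[k]]
    cfg[[k]] <<- if (is.logical(v)) v else tolower(v) %in% c("true", "1", "yes")
  }
  for (k in c("gain_rate", "loss_rate", "root_presence_prob",
              "within_clade_depth", "between_clade_depth", "sub_rate",
              "min_alignment_columns", "min_percent_identity",
              "evalue_threshold", "lambda_stat", "k_stat")) num(k)
  for (k in c("n_clades", "leaves_per_clade", "n_families", "seed",
              "root_len_min", "root_len_max", "gap_open", "gap_extend",
              "newick_precision")) int(k)
  for (k in c("run_bbh", "simulate")) lgl(k)
  if (!cfg$linkage %in% c("complete", "single", "average", "ward"))
    stop("linkage must be complete/single/average/ward")
  if (cfg$min_alignment_columns < 0 || cfg$min_percent_identity < 0 ||
      cfg$min_percent_identity > 100)
    stop("homology thresholds out of range")
  if (cfg$evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Unknown keys are rejected.
#'
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  do.call(pipeline_config, setNames(as.list(vals), keys))
}

write_config <- function(cfg, path) {
  keys <- sort(names(cfg))
  vals <- vapply(cfg[keys], function(v)
    if (is.numeric(v) && !is.integer(v)) format(v, digits = 15L)
    else as.character(v), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(keys, vals, sep = " = "), con, sep = "\n")
  invisible(path)
}

#' Run the full gene-content pipeline
#'
#' Chains simulate -> reciprocal-best-hit homology -> reference
#' assignment -> phyletic matrix -> Euclidean distances -> hierarchical
#' clustering -> clade recovery, writing every intermediate under
#' `cfg$outdir` together with the resolved configuration and a manifest
#' of per-stage outputs with MD5 checksums. Fully deterministic given
#' the config seed. With `simulate = FALSE` the proteomes, reference
#' database and clade labels must already exist in `outdir` (pre-flight
#' checked before any stage runs).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest data.frame (`stage`, `path`, `md5`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "proteomes"), showWarnings = FALSE)
  dir.create(file.path(out, "refdb"), showWarnings = FALSE)
  if (!cfg$simulate) {
    needed <- c(file.path(out, "clades.tsv"),
                file.path(out, "refdb", "groups.tsv"),
                file.path(out, "refdb", "members.fasta"))
    miss <- needed[!file.exists(needed)]
    if (length(miss) || length(list.files(file.path(out, "proteomes"),
                                          pattern = "\\.fasta$")) == 0L)
      stop("simulate = FALSE but inputs are missing: ",
           paste(c(miss, "proteomes/*.fasta"), collapse = ", "))
  }
  write_config(cfg, file.path(out, "config_resolved.txt"))
  manifest <- list()
  note <- function(stage, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage,
      path = if (startsWith(path, paste0(out, "/")))
               substring(path, nchar(out) + 2L) else path,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)

  scoring <- scoring_scheme(gap_open = cfg$gap_open,
                            gap_extend = cfg$gap_extend,
                            lambda_stat = cfg$lambda_stat,
                            k_stat = cfg$k_stat)
  allowed <- strsplit(cfg$categories, ",", fixed = TRUE)[[1]]
  allowed <- trimws(allowed)

  if (cfg$simulate) {
    tree <- sample_tree(cfg$n_clades, cfg$leaves_per_clade,
                        cfg$within_clade_depth, cfg$between_clade_depth,
                        seed = cfg$seed)
    gl <- gain_loss_params(cfg$gain_rate, cfg$loss_rate, cfg$n_families,
                           root_presence_prob =
                             if (is.na(cfg$root_presence_prob)) NULL
                             else cfg$root_presence_prob,
                           master_seed = cfg$seed)
    truth <- evolve_content(tree, gl)
    prot <- evolve_proteomes(tree, truth,
                             seq_evol_params(cfg$sub_rate, cfg$root_len_min,
                                             cfg$root_len_max,
                                             seed = derive_seed(cfg$seed, 7L)))
    writeLines(tree$newick, file.path(out, "tree.nwk"))
    note("simulate", file.path(out, "tree.nwk"))
    write_tsv_lf(data.frame(taxon = names(tree$clades),
                            clade = unname(tree$clades)),
                 file.path(out, "clades.tsv"))
    note("simulate", file.path(out, "clades.tsv"))
    write_matrix_tsv(truth$matrix, file.path(out, "truth_matrix.tsv"))
    note("simulate", file.path(out, "truth_matrix.tsv"))
    tr <- truth$trace
    tr$position <- fmt_num(tr$position, 6L)
    write_tsv_lf(tr, file.path(out, "trace.tsv"))
    note("simulate", file.path(out, "trace.tsv"))
    for (tx in names(prot$proteomes)) {
      p <- file.path(out, "proteomes", paste0(tx, ".fasta"))
      seqs <- prot$proteomes[[tx]]
      if (length(seqs)) names(seqs) <- paste(tx, names(seqs), sep = "|")
      write_fasta(seqs, p)
      note("simulate", p)
    }
    refdb <- reference_from_roots(prot)
    write_reference_db(refdb, file.path(out, "refdb", "groups.tsv"),
                       file.path(out, "refdb", "members.fasta"))
    note("simulate", file.path(out, "refdb", "groups.tsv"))
    note("simulate", file.path(out, "refdb", "members.fasta"))
    message(sprintf("[simulate] %d taxa, %d families, %d trace events",
                    nrow(truth$matrix), ncol(truth$matrix), nrow(truth$trace)))
  }

  # load stage inputs from disk so simulate/no-simulate runs share a path
  prot_files <- sort(list.files(file.path(out, "proteomes"),
                                pattern = "\\.fasta$", full.names = TRUE))
  proteomes <- lapply(prot_files, function(p) {
    seqs <- suppressWarnings(read_fasta(p))
    names(seqs) <- sub("^[^|]*\\|", "", names(seqs))
    seqs
  })
  names(proteomes) <- sub("\\.fasta$", "", basename(prot_files))
  clades_df <- read.delim(file.path(out, "clades.tsv"),
                          stringsAsFactors = FALSE)
  clade_labels <- setNames(clades_df$clade, clades_df$taxon)
  refdb <- read_reference_db(file.path(out, "refdb", "groups.tsv"),
                             file.path(out, "refdb", "members.fasta"))

  if (cfg$run_bbh) {
    pairs <- all_vs_all_bbh(proteomes, scoring,
                            cfg$min_alignment_columns,
                            cfg$min_percent_identity)
    pp <- pairs
    pp$percent_identity <- fmt_num(pp$percent_identity, 6L)
    pp$evalue <- formatC(pp$evalue, format = "e", digits = 6L)
    write_tsv_lf(pp, file.path(out, "bbh_pairs.tsv"))
    note("bbh", file.path(out, "bbh_pairs.tsv"))
    groups <- build_homolog_groups(pairs)
    write_tsv_lf(groups, file.path(out, "homolog_groups.tsv"))
    note("bbh", file.path(out, "homolog_groups.tsv"))
    message(sprintf("[bbh] %d reciprocal pairs, %d homolog groups",
                    nrow(pairs), length(unique(groups$group_id))))
  }

  refdb_f <- filter_reference_by_category(refdb, allowed)
  assignments <- lapply(proteomes, function(p)
    suppressMessages(assign_to_reference(p, refdb_f, scoring,
                                         cfg$evalue_threshold)))
  asg_df <- do.call(rbind, Map(function(tx, df)
    if (nrow(df)) data.frame(taxon = tx, df, stringsAsFactors = FALSE)
    else NULL, names(assignments), assignments))
  if (is.null(asg_df))
    asg_df <- data.frame(taxon = character(0), protein = character(0),
                         group_id = character(0), evalue = numeric(0))
  asg_out <- asg_df
  asg_out$evalue <- formatC(asg_out$evalue, format = "e", digits = 6L)
  write_tsv_lf(asg_out, file.path(out, "assignments.tsv"))
  note("assign", file.path(out, "assignments.tsv"))
  message(sprintf("[assign] %d proteins assigned across %d taxa",
                  nrow(asg_df), length(proteomes)))

  mat <- build_matrix(assignments, sort(refdb_f$groups$group_id))
  write_matrix_tsv(mat, file.path(out, "matrix.tsv"))
  note("matrix", file.path(out, "matrix.tsv"))
  message(sprintf("[matrix] %d x %d cells, %d set",
                  nrow(mat), ncol(mat), sum(mat)))

  D <- euclidean_distances(mat)
  write_distances_tsv(D, file.path(out, "distances.tsv"))
  note("cluster", file.path(out, "distances.tsv"))
  dend <- agglomerative_cluster(D, cfg$linkage)
  nwk <- to_newick(dend, cfg$newick_precision)
  con <- file(file.path(out, "dendrogram.nwk"), open = "wb")
  writeLines(nwk, con, sep = "\n"); close(con)
  note("cluster", file.path(out, "dendrogram.nwk"))

  ref_tree <- if (file.exists(file.path(out, "tree.nwk")))
    file.path(out, "tree.nwk") else NULL
  rec <- compare_clades(dend, clade_labels, ref_tree)
  rec_df <- data.frame(
    clade = names(rec$monophyletic),
    monophyletic = unname(rec$monophyletic), stringsAsFactors = FALSE)
  write_tsv_lf(rec_df, file.path(out, "recovery.tsv"))
  note("evaluate", file.path(out, "recovery.tsv"))
  message(sprintf("[evaluate] %d/%d clades monophyletic%s",
                  rec$n_clades_recovered, length(rec$monophyletic),
                  if (!is.null(rec$rf))
                    sprintf(", RF = %d (clade-level %s)", rec$rf,
                            as.character(rec$rf_clade)) else ""))

  manifest <- do.call(rbind, manifest)
  write_tsv_lf(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}
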