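# File formats and pipeline glue: CSV pedigree/phenotypes, TSV dosage and
# PLINK-style .ped/.map genotypes, validated run configuration, and the
# staged, resumable pipeline driver.

#' Write / read a pedigree as CSV
#'
#' Columns id, sire, dam, sex, generation, hatch; unknown parents are
#' written as "0". The reader re-orders rows topologically (parents before
#' offspring) and detects cycles.
#'
#' @param pedigree pedigree data.frame.
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- pedigree
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  write.table(ped, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @return \code{read_pedigree} returns a topologically sorted pedigree
#'   data.frame with NA for unknown parents.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    colClasses = "character")
  ped <- normalize_pedigree_parents(ped)
  if ("hatch" %in% names(ped)) ped$hatch <- as.integer(ped$hatch)
  known <- ped$id
  bad <- setdiff(c(ped$sire, ped$dam), c(known, NA))
  if (length(bad)) stop("unknown parent id(s): ", paste(bad, collapse = ", "))
  topological_sort_pedigree(ped)
}

# Stable topological sort: repeatedly sweep the remaining rows in their
# original order, placing every row whose parents are already placed. An
# already-sorted pedigree comes back unchanged; a sweep that places nothing
# means a cycle (an individual its own ancestor).
topological_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  placed <- logical(n)
  out <- integer(0)
  while (length(out) < n) {
    ready <- which(!placed &
                     (si == 0L | placed[pmax(si, 1L)]) &
                     (di == 0L | placed[pmax(di, 1L)]))
    if (length(ready) == 0L)
      stop("pedigree contains a cycle (an individual is its own ancestor)")
    placed[ready] <- TRUE
    out <- c(out, ready)
  }
  ped2 <- ped[out, , drop = FALSE]
  rownames(ped2) <- NULL
  ped2
}

#' Write / read phenotypes as CSV
#'
#' Columns id, trait, y, sex, hatch (and tbv when simulated). The reader
#' rejects duplicate (id, trait) rows.
#'
#' @param phenos phenotype data.frame (or list of per-trait data.frames).
#' @param path file path.
#' @export
write_phenotypes <- function(phenos, path) {
  if (is.list(phenos) && !is.data.frame(phenos))
    phenos <- do.call(rbind, lapply(phenos, as.data.frame))
  write.table(phenos, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (anyDuplicated(ph[, c("id", "trait")]))
    stop("duplicate (id, trait) phenotype rows")
  ph
}

#' Write genotypes
#'
#' Two dialects: a tab-separated dosage matrix (header row of SNP ids, first
#' column of individual ids, missing as NA) and a PLINK-compatible
#' .ped/.map pair. The .map carries chromosome, SNP id, position in cM and
#' two extra columns naming the reference and alternative allele; dosages
#' count reference alleles, missing genotypes are written "0 0".
#'
#' @param geno a \code{genotypes} object.
#' @param path output path (for ped format, the basename; .ped and .map are
#'   appended).
#' @param format "tsv" or "ped".
#' @param ref,alt allele letters used for the .ped encoding.
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "ped"),
                            ref = "A", alt = "C") {
  format <- match.arg(format)
  d <- geno$dosage
  if (format == "tsv") {
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  map <- geno$map
  refs <- rep(ref, ncol(d)); alts <- rep(alt, ncol(d))
  gen_str <- matrix("0 0", nrow(d), ncol(d))
  gen_str[!is.na(d) & d == 2] <- paste(ref, ref)
  gen_str[!is.na(d) & d == 1] <- paste(ref, alt)
  gen_str[!is.na(d) & d == 0] <- paste(alt, alt)
  ped_lines <- paste(rownames(d), rownames(d), "0", "0", "0", "-9",
                     apply(gen_str, 1, paste, collapse = " "))
  writeLines(ped_lines, paste0(path, ".ped"))
  write.table(data.frame(map$chr, map$snp, map$pos_cm, 0L, refs, alts),
              paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes
#'
#' @param path file path; for ped format the basename shared by .ped/.map.
#' @param format "auto" (by extension), "tsv" or "ped".
#' @return a \code{genotypes} object.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "ped")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path)) "tsv"
              else if (file.exists(paste0(path, ".ped"))) "ped"
              else "tsv"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    d <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(d) <- "double"
    rownames(d) <- df$id
    if (anyDuplicated(df$id)) stop("duplicate individual ids")
    map <- data.frame(snp = colnames(d), chr = 1L,
                      pos_cm = seq_len(ncol(d)), stringsAsFactors = FALSE)
    return(genotypes(d, map))
  }
  map_raw <- read.table(paste0(path, ".map"), sep = "\t",
                        stringsAsFactors = FALSE)
  names(map_raw) <- c("chr", "snp", "pos_cm", "pos_bp", "ref", "alt")[seq_len(ncol(map_raw))]
  if (is.null(map_raw$ref)) stop(".map must declare reference alleles (column 5)")
  lines <- readLines(paste0(path, ".ped"))
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map_raw)
  n <- length(toks)
  d <- matrix(NA_real_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6 + 2 * m) stop("ragged .ped row ", i)
    ids[i] <- tk[2]
    a1 <- tk[seq(7, by = 2, length.out = m)]
    a2 <- tk[seq(8, by = 2, length.out = m)]
    ok <- c(a1, a2) %in% c("A", "C", "G", "T", "0")
    if (!all(ok)) stop("allele codes outside {A,C,G,T,0} in row ", i)
    miss <- a1 == "0" | a2 == "0"
    d[i, ] <- (a1 == map_raw$ref) + (a2 == map_raw$ref)
    d[i, miss] <- NA_real_
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  rownames(d) <- ids
  colnames(d) <- map_raw$snp
  genotypes(d, map_raw[, c("snp", "chr", "pos_cm")])
}

#' Validated run configuration
#'
#' Defaults are the study's design constants: cohorts 20/51/511, 8 half-sib
#' families, 4 hatches, QC thresholds 0.95/0.01, 4-fold cross-validation in
#' both scenarios, mixture proportions 0.889/0.1/0.01/0.001 and the
#' production MCMC schedule 50,000/20,000/20. Unknown keys are rejected.
#'
#' @param ... overrides of the default keys.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_per_line = 10, n_snps = 5000, n_chromosomes = 10, map_length_cm = 100,
    divergence = 0.3,
    n_f1 = 51, n_sires_f1 = 8, n_f2 = 511, n_hatches = 4,
    traits = c("BW6", "BW12", "EP", "BMP", "LMP"), n_qtl = 200,
    min_call_rate = 0.95, min_maf = 0.01,
    models = c("blup", "gblup", "lasso", "mix4"),
    scenarios = c("family", "random"), k = 4,
    pi = c(0.889, 0.1, 0.01, 0.001),
    mcmc = list(n_iter = 50000, burnin = 20000, thin = 20),
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$n_f2 >= 1, cfg$k >= 2, cfg$divergence >= 0, cfg$divergence < 1,
            cfg$min_call_rate >= 0, cfg$min_call_rate <= 1,
            cfg$min_maf >= 0, cfg$min_maf <= 1,
            abs(sum(cfg$pi) - 1) < 1e-12,
            cfg$mcmc$burnin < cfg$mcmc$n_iter, cfg$mcmc$thin >= 1)
  if (!all(cfg$traits %in% names(chicken_traits())))
    stop("unknown trait(s) in config")
  structure(cfg, class = "run_config")
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg))
}

# Run `fun` unless all `outputs` exist and the stored hash of `key` matches.
run_stage <- function(name, key, outputs, out_dir, fun) {
  hash_file <- file.path(out_dir, paste0(".stage_", name, ".hash"))
  h <- object_hash(key)
  if (all(file.exists(outputs)) && file.exists(hash_file) &&
      identical(readLines(hash_file, warn = FALSE)[1], h)) {
    pipeline_log(name, "outputs up to date, skipping")
    return(invisible(FALSE))
  }
  pipeline_log(name, "running")
  fun()
  writeLines(h, hash_file)
  invisible(TRUE)
}

#' Run the full pipeline: simulate, QC, relationship matrices,
#' cross-validation, report
#'
#' Stage outputs are plain-text files under \code{out_dir}; a stage is
#' skipped when its outputs exist and the hash of its slice of the
#' configuration matches the previous run, so changing one stage's
#' parameters recomputes only that stage and everything downstream. A
#' manifest (config, seed, package version) is written alongside.
#'
#' @param config a \code{run_config}.
#' @param out_dir output directory (created if absent).
#' @return the \code{eval_report} of the cross-validation stage, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(config)

  sim_key <- cfg[c("n_per_line", "n_snps", "n_chromosomes", "map_length_cm",
                   "divergence", "n_f1", "n_sires_f1", "n_f2", "n_hatches",
                   "traits", "n_qtl", "seed")]
  ped_file <- file.path(out_dir, "pedigree.csv")
  gen_file <- file.path(out_dir, "genotypes.tsv")
  phe_file <- file.path(out_dir, "phenotypes.csv")
  run_stage("simulate", sim_key, c(ped_file, gen_file, phe_file), out_dir, function() {
    pop <- simulate_population(
      n_per_line = cfg$n_per_line, n_snps = cfg$n_snps,
      n_chromosomes = cfg$n_chromosomes, map_length_cm = cfg$map_length_cm,
      divergence = cfg$divergence, n_f1 = cfg$n_f1,
      n_sires_f1 = cfg$n_sires_f1, n_f2 = cfg$n_f2,
      n_hatches = cfg$n_hatches,
      traits = chicken_traits(n_qtl = cfg$n_qtl)[cfg$traits],
      seed = cfg$seed)
    write_pedigree(pop$pedigree, ped_file)
    write_genotypes(pop$genotypes, gen_file, format = "tsv")
    write_phenotypes(pop$phenotypes, phe_file)
  })

  qc_key <- c(sim_key, cfg[c("min_call_rate", "min_maf")])
  qc_file <- file.path(out_dir, "qc_report.json")
  qcg_file <- file.path(out_dir, "genotypes_qc.tsv")
  run_stage("qc", qc_key, c(qc_file, qcg_file), out_dir, function() {
    geno <- read_genotypes(gen_file, format = "tsv")
    qc <- filter_snps(geno, cfg$min_call_rate, cfg$min_maf)
    qc_report_json(qc$report, qc_file)
    write_genotypes(qc$genotypes, qcg_file, format = "tsv")
  })

  rel_key <- qc_key
  a_file <- file.path(out_dir, "A.tsv")
  g_file <- file.path(out_dir, "G.tsv")
  run_stage("relmat", rel_key, c(a_file, g_file), out_dir, function() {
    ped <- read_pedigree(ped_file)
    geno <- impute_missing(read_genotypes(qcg_file, format = "tsv"))
    write_relmat(pedigree_a_matrix(ped), a_file)
    write_relmat(genomic_g_matrix(geno), g_file)
  })

  cv_key <- c(qc_key, cfg[c("models", "scenarios", "k", "pi", "mcmc")])
  report_file <- file.path(out_dir, "eval_report.csv")
  report <- NULL
  run_stage("crossval", cv_key, report_file, out_dir, function() {
    ped <- read_pedigree(ped_file)
    geno <- read_genotypes(gen_file, format = "tsv")
    ph <- read_phenotypes(phe_file)
    pop <- list(pedigree = ped, genotypes = geno,
                phenotypes = split(ph, ph$trait))
    report <<- run_study(
      pop, traits = cfg$traits, models = cfg$models,
      scenarios = cfg$scenarios, k = cfg$k,
      mcmc = mcmc_config(cfg$mcmc$n_iter, cfg$mcmc$burnin, cfg$mcmc$thin),
      qc_thresholds = list(min_call_rate = cfg$min_call_rate,
                           min_maf = cfg$min_maf),
      seed = cfg$seed)
    write_eval_report(report, report_file)
  })
  if (is.null(report) && file.exists(report_file)) {
    pipeline_log("crossval", "reusing existing evaluation report")
  }

  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("chickgp")),
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
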