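# Population simulator: two divergent founder lines crossed to a
# three-generation F2 intercross with half-sib family structure, marker
# genotypes dropped through the pedigree under a Haldane meiosis model,
# and additive quantitative traits with sex and hatch fixed effects.

#' Build a SNP map
#'
#' SNPs are spread as evenly as possible over chromosomes, with positions
#' drawn uniformly on each chromosome and sorted, so map positions are
#' non-decreasing within a chromosome.
#'
#' @param n_snps total number of SNPs.
#' @param n_chromosomes number of (autosomal) chromosomes.
#' @param map_length_cm genetic length of each chromosome in centimorgans.
#' @return data.frame with columns snp, chr, pos_cm.
#' @export
make_snp_map <- function(n_snps, n_chromosomes, map_length_cm) {
  stopifnot(n_snps >= 1, n_chromosomes >= 1, map_length_cm >= 0)
  per_chr <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  extra <- n_snps %% n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chr <- rep(seq_len(n_chromosomes), per_chr)
  pos <- unlist(lapply(per_chr, function(k) sort(runif(k, 0, map_length_cm))))
  data.frame(
    snp = sprintf("snp%05d", seq_len(n_snps)),
    chr = chr,
    pos_cm = pos,
    stringsAsFactors = FALSE
  )
}

#' Simulate two divergent founder lines
#'
#' Per SNP an ancestral allele frequency is drawn uniform on (0.05, 0.95);
#' each line's frequency is then drawn from a Beta distribution centred on
#' the ancestral frequency with drift parametrised by \code{divergence}
#' (a Balding-Nichols construction: shape parameters
#' \code{p(1-F)/F} and \code{(1-p)(1-F)/F} with \code{F = divergence}).
#' \code{divergence = 0} gives identical lines. Founder haplotypes are
#' independent Bernoulli draws at the line frequency, so founders are in
#' Hardy-Weinberg equilibrium within line.
#'
#' @param n_per_line founders per line (sexes alternate within line).
#' @param n_snps number of SNPs.
#' @param n_chromosomes number of chromosomes.
#' @param map_length_cm per-chromosome map length (cM).
#' @param divergence between-line allele-frequency divergence, in [0, 1).
#' @param seed integer seed (optional).
#' @return object of class \code{founder_pop}: haplotype matrices
#'   \code{hap1}/\code{hap2} (individual x SNP), a \code{genotypes} object
#'   (see \code{\link{genotypes}}), an F0-only pedigree, the line label of
#'   each founder, and the ancestral and per-line allele frequencies.
#' @export
simulate_founders <- function(n_per_line = 10, n_snps = 5000,
                              n_chromosomes = 10, map_length_cm = 100,
                              divergence = 0.3, seed = NULL) {
  if (n_per_line < 1 || n_snps < 1 || n_chromosomes < 1)
    stop("counts must be positive")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  set_seed_if(seed)

  map <- make_snp_map(n_snps, n_chromosomes, map_length_cm)
  p_anc <- runif(n_snps, 0.05, 0.95)
  draw_line_freq <- function() {
    if (divergence == 0) return(p_anc)
    f <- divergence
    rbeta(n_snps, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }
  p_line <- cbind(A = draw_line_freq(), B = draw_line_freq())

  n <- 2L * n_per_line
  ids <- sprintf("F0_%03d", seq_len(n))
  line <- rep(c("A", "B"), each = n_per_line)
  sex <- rep(rep(c("M", "F"), length.out = n_per_line), 2L)

  hap_for <- function(p) matrix(rbinom(n_per_line * n_snps, 1L, rep(p, each = n_per_line)),
                                nrow = n_per_line, ncol = n_snps)
  hap1 <- rbind(hap_for(p_line[, "A"]), hap_for(p_line[, "B"]))
  hap2 <- rbind(hap_for(p_line[, "A"]), hap_for(p_line[, "B"]))
  rownames(hap1) <- rownames(hap2) <- ids
  colnames(hap1) <- colnames(hap2) <- map$snp

  ped <- data.frame(
    id = ids, sire = NA_character_, dam = NA_character_,
    sex = sex, generation = "F0", hatch = 1L,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      hap1 = hap1, hap2 = hap2,
      genotypes = genotypes(hap1 + hap2, map),
      pedigree = ped, line = setNames(line, ids),
      p_ancestral = p_anc, p_line = p_line, map = map
    ),
    class = "founder_pop"
  )
}

#' Genotype container
#'
#' A dosage matrix (rows = individuals, columns = SNPs, entries 0/1/2 or NA
#' for missing) together with its SNP map.
#'
#' @param dosage numeric matrix with row and column names.
#' @param map data.frame with columns snp, chr, pos_cm matching the columns.
#' @param imputed optional logical matrix flagging imputed entries.
#' @return object of class \code{genotypes}.
#' @export
genotypes <- function(dosage, map, imputed = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  if (anyDuplicated(rownames(dosage))) stop("duplicate individual ids")
  if (!identical(colnames(dosage), map$snp))
    stop("map does not match dosage columns")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  bad <- unlist(lapply(split(map$pos_cm, map$chr), is.unsorted))
  if (any(bad)) stop("map positions must be non-decreasing within chromosome")
  structure(list(dosage = dosage, map = map, imputed = imputed),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d individuals x %d SNPs on %d chromosomes (%d missing)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chr)),
              sum(is.na(x$dosage))))
  invisible(x)
}

#' Drop one gamete through meiosis (Haldane model)
#'
#' Crossover counts per chromosome are Poisson with mean length/100 cM and
#' crossover positions are uniform (no interference); the gamete copies one
#' parental strand, switching at each crossover, starting from a random
#' strand per chromosome.
#'
#' @param hap1,hap2 the parent's two haplotype vectors (one allele per SNP).
#' @param map SNP map data.frame (snp, chr, pos_cm).
#' @return integer vector of gamete alleles.
#' @export
drop_gamete <- function(hap1, hap2, map) {
  if (nrow(map) == 0L) stop("empty map")
  out <- integer(nrow(map))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    pos <- map$pos_cm[idx]
    len <- max(pos)
    ncx <- rpois(1L, len / 100)
    start <- sample.int(2L, 1L) - 1L
    if (ncx == 0L) {
      phase <- rep(start, length(idx))
    } else {
      cuts <- sort(runif(ncx, 0, len))
      phase <- (start + findInterval(pos, cuts)) %% 2L
    }
    out[idx] <- ifelse(phase == 0L, hap1[idx], hap2[idx])
  }
  out
}

#' Design and realise the three-generation intercross
#'
#' F1 are produced by reciprocal between-line matings of the founders; F2 by
#' mating each of \code{n_sires_f1} selected F1 males to several F1 females
#' (dams are never shared between sires), giving exactly \code{n_sires_f1}
#' half-sib sire families whose sizes differ by at most one (balanced
#' remainder of the integer division \code{n_f2 / n_sires_f1}). Hatch labels
#' are assigned round-robin within family. Genotypes of F1 and F2 are
#' obtained by gamete dropping (\code{\link{drop_gamete}}).
#'
#' @param founders a \code{founder_pop}.
#' @param n_f1 number of F1 birds.
#' @param n_sires_f1 number of F1 sires, i.e. half-sib families.
#' @param n_f2 number of F2 birds.
#' @param n_hatches number of hatch batches (round-robin within family).
#' @param seed integer seed (optional).
#' @return object of class \code{sim_population}: full pedigree, haplotypes
#'   and \code{genotypes} for all individuals, the SNP map, per-F2 family
#'   label, and the founder metadata.
#' @export
make_cross_design <- function(founders, n_f1 = 51, n_sires_f1 = 8,
                              n_f2 = 511, n_hatches = 4, seed = NULL) {
  stopifnot(inherits(founders, "founder_pop"))
  if (n_f1 < 1 || n_sires_f1 < 1 || n_f2 < 1) stop("counts must be positive")
  set_seed_if(seed)

  ped0 <- founders$pedigree
  line <- founders$line
  males_A <- ped0$id[ped0$sex == "M" & line == "A"]
  fems_A  <- ped0$id[ped0$sex == "F" & line == "A"]
  males_B <- ped0$id[ped0$sex == "M" & line == "B"]
  fems_B  <- ped0$id[ped0$sex == "F" & line == "B"]
  if (length(males_A) == 0 || length(fems_B) == 0 ||
      length(males_B) == 0 || length(fems_A) == 0)
    stop("infeasible design: need both sexes in both founder lines")

  # reciprocal between-line mating pairs
  pairs <- rbind(
    cbind(sire = males_A, dam = fems_B[(seq_along(males_A) - 1L) %% length(fems_B) + 1L]),
    cbind(sire = males_B, dam = fems_A[(seq_along(males_B) - 1L) %% length(fems_A) + 1L])
  )
  f1_ids <- sprintf("F1_%03d", seq_len(n_f1))
  # F1 are produced as alternating male/female broods of the mating pairs,
  # two consecutive F1 per couple; the first male of every couple comes
  # first, so the selected F1 sires descend from distinct founder couples
  # whenever enough couples exist (a broad-base half-sib design; sires that
  # are full sibs would leak pedigree information across sire families)
  f1_pair <- ((seq_len(n_f1) - 1L) %/% 2L) %% nrow(pairs) + 1L
  f1_sex <- rep(c("M", "F"), length.out = n_f1)

  f1_males <- f1_ids[f1_sex == "M"]
  f1_fems  <- f1_ids[f1_sex == "F"]
  if (length(f1_males) < n_sires_f1)
    stop("infeasible design: fewer F1 males than requested sires")
  if (length(f1_fems) < n_sires_f1)
    stop("infeasible design: need at least one F1 dam per sire")
  sires <- f1_males[seq_len(n_sires_f1)]
  # dams dealt to sires in couple order so that (a) no sire is mated to a
  # full sib (no own-couple dams; conflicts resolved by swapping) and
  # (b) each sire's dams come from distinct couples where the base allows;
  # every dam belongs to exactly one sire, so half-sib families never share
  # parents
  fem_couple <- f1_pair[match(f1_fems, f1_ids)]
  ord <- order(fem_couple)
  fems_sorted <- f1_fems[ord]
  cpl <- fem_couple[ord]
  sire_of <- rep(seq_len(n_sires_f1), length.out = length(fems_sorted))
  sire_couple <- f1_pair[match(sires, f1_ids)]
  for (j in which(sire_couple[sire_of] == cpl)) {
    k <- which(sire_couple[sire_of] != cpl[j] &
                 cpl != sire_couple[sire_of[j]] & seq_along(cpl) != j)
    if (length(k)) {
      k <- k[1]
      tmp <- sire_of[j]; sire_of[j] <- sire_of[k]; sire_of[k] <- tmp
    }
  }
  dam_of_sire <- split(fems_sorted,
                       factor(sire_of, levels = seq_len(n_sires_f1)))
  if (any(vapply(dam_of_sire, length, 1L) == 0L))
    stop("infeasible design: a sire received no dams")

  # balanced-remainder family sizes: n_f2 = q * s + r -> r families of q+1
  q <- n_f2 %/% n_sires_f1
  r <- n_f2 %% n_sires_f1
  fam_sizes <- rep(q, n_sires_f1)
  if (r > 0) fam_sizes[seq_len(r)] <- q + 1L

  f2_ids <- sprintf("F2_%04d", seq_len(n_f2))
  f2_sire <- rep(sires, fam_sizes)
  f2_dam <- unlist(lapply(seq_len(n_sires_f1), function(s) {
    d <- dam_of_sire[[s]]
    d[(seq_len(fam_sizes[s]) - 1L) %% length(d) + 1L]
  }))
  f2_hatch <- unlist(lapply(fam_sizes, function(k) (seq_len(k) - 1L) %% n_hatches + 1L))
  f2_sex <- sample(rep(c("M", "F"), length.out = n_f2))

  ped <- rbind(
    ped0,
    data.frame(id = f1_ids, sire = pairs[f1_pair, "sire"],
               dam = pairs[f1_pair, "dam"], sex = f1_sex,
               generation = "F1", hatch = 1L, stringsAsFactors = FALSE),
    data.frame(id = f2_ids, sire = f2_sire, dam = f2_dam, sex = f2_sex,
               generation = "F2", hatch = f2_hatch, stringsAsFactors = FALSE)
  )
  rownames(ped) <- NULL

  # gamete-drop genotypes down the pedigree (topological order)
  map <- founders$map
  n_all <- nrow(ped)
  m <- nrow(map)
  hap1 <- matrix(0L, n_all, m, dimnames = list(ped$id, map$snp))
  hap2 <- hap1
  hap1[rownames(founders$hap1), ] <- founders$hap1
  hap2[rownames(founders$hap2), ] <- founders$hap2
  for (i in which(ped$generation != "F0")) {
    s <- ped$sire[i]; d <- ped$dam[i]
    hap1[i, ] <- drop_gamete(hap1[s, ], hap2[s, ], map)
    hap2[i, ] <- drop_gamete(hap1[d, ], hap2[d, ], map)
  }

  structure(
    list(
      pedigree = ped,
      hap1 = hap1, hap2 = hap2,
      genotypes = genotypes(hap1 + hap2, map),
      map = map,
      family = setNames(f2_sire, f2_ids),
      founders = founders
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$pedigree$generation)
  cat(sprintf("sim_population: %s individuals (%s), %d SNPs, %d half-sib F2 families\n",
              nrow(x$pedigree),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
              nrow(x$map), length(unique(x$family))))
  invisible(x)
}

#' Additive trait architecture
#'
#' @param name trait label.
#' @param h2 target narrow-sense heritability in [0, 1].
#' @param mean population mean (trait units).
#' @param sd_p target phenotypic standard deviation (trait units).
#' @param n_qtl number of QTL drawn uniformly among the SNPs.
#' @param sex_effect additive effect of sex M over F (trait units).
#' @param hatch_effects effect of each hatch level (first is the reference).
#' @return object of class \code{trait_architecture}.
#' @export
trait_architecture <- function(name, h2, mean = 0, sd_p = 1, n_qtl = 200,
                               sex_effect = 0.5 * sd_p,
                               hatch_effects = c(0, 0.2, -0.2, 0.1) * sd_p) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (h2 > 0 && n_qtl < 1) stop("need at least one QTL when h2 > 0")
  structure(list(name = name, h2 = h2, mean = mean, sd_p = sd_p,
                 n_qtl = n_qtl, sex_effect = sex_effect,
                 hatch_effects = hatch_effects),
            class = "trait_architecture")
}

#' Default trait set: growth and carcass traits of the F2 cross
#'
#' Five traits with the population means, phenotypic standard deviations and
#' heritabilities of body weight at 6 and 12 weeks (BW6, BW12, in g),
#' eviscerating percentage (EP), breast muscle percentage (BMP) and leg
#' muscle percentage (LMP).
#'
#' @param n_qtl QTL count per trait.
#' @return named list of \code{trait_architecture} objects.
#' @export
chicken_traits <- function(n_qtl = 200) {
  spec <- list(
    BW6  = c(mean = 802.33,  sd = 133.58, h2 = 0.26),
    BW12 = c(mean = 2027.06, sd = 360.27, h2 = 0.13),
    EP   = c(mean = 66.57,   sd = 1.82,   h2 = 0.44),
    BMP  = c(mean = 17.40,   sd = 1.43,   h2 = 0.39),
    LMP  = c(mean = 23.73,   sd = 2.57,   h2 = 0.39)
  )
  lapply(setNames(names(spec), names(spec)), function(tr) {
    s <- spec[[tr]]
    trait_architecture(tr, h2 = s[["h2"]], mean = s[["mean"]],
                       sd_p = s[["sd"]], n_qtl = n_qtl)
  })
}

#' Simulate phenotypes for the F2 cohort
#'
#' True breeding values are sums of QTL dosages times additive effects; QTL
#' are drawn uniformly among the SNPs, raw effects are standard normal and
#' rescaled so the realised additive variance in the F2 cohort equals
#' \code{h2 * sd_p^2}; the residual variance is \code{(1 - h2) * sd_p^2}.
#' Phenotypes (F2 only) are mean + sex effect + hatch effect + TBV + normal
#' residual.
#'
#' @param population a \code{sim_population}.
#' @param architecture a \code{trait_architecture}.
#' @param seed integer seed (optional).
#' @return data.frame (class \code{phenotypes}) with columns id, trait, y,
#'   sex, hatch, tbv; one row per F2 individual. The realised QTL indices and
#'   effects are attached as attributes \code{qtl} and \code{effects}, and
#'   the residual variance as \code{sigma_e2}.
#' @export
simulate_phenotypes <- function(population, architecture, seed = NULL) {
  stopifnot(inherits(population, "sim_population"),
            inherits(architecture, "trait_architecture"))
  set_seed_if(seed)
  ped <- population$pedigree
  f2 <- ped$generation == "F2"
  dose <- population$genotypes$dosage
  a <- architecture
  sigma_p2 <- a$sd_p^2

  if (a$h2 > 0) {
    qtl <- sort(sample.int(ncol(dose), min(a$n_qtl, ncol(dose))))
    eff <- rnorm(length(qtl))
    tbv_raw <- drop(dose[, qtl, drop = FALSE] %*% eff)
    v <- var(tbv_raw[f2])
    if (!is.finite(v) || v <= 0)
      stop("realised QTL variance is not positive; cannot scale to target h2")
    eff <- eff * sqrt(a$h2 * sigma_p2 / v)
    tbv <- drop(dose[, qtl, drop = FALSE] %*% eff)
  } else {
    qtl <- integer(0)
    eff <- numeric(0)
    tbv <- rep(0, nrow(dose))
  }
  names(tbv) <- rownames(dose)

  sigma_e2 <- (1 - a$h2) * sigma_p2
  ids <- ped$id[f2]
  sexv <- ped$sex[f2]
  hatchv <- ped$hatch[f2]
  hatch_eff <- a$hatch_effects[(hatchv - 1L) %% length(a$hatch_effects) + 1L]
  y <- a$mean + ifelse(sexv == "M", a$sex_effect, 0) + hatch_eff +
    tbv[ids] + rnorm(length(ids), 0, sqrt(sigma_e2))

  out <- data.frame(id = ids, trait = a$name, y = y, sex = sexv,
                    hatch = hatchv, tbv = tbv[ids],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "qtl") <- qtl
  attr(out, "effects") <- eff
  attr(out, "sigma_e2") <- sigma_e2
  attr(out, "tbv_all") <- tbv
  class(out) <- c("phenotypes", "data.frame")
  out
}

#' One-call simulation of the full study population
#'
#' Convenience wrapper: founders, cross design, gamete dropping and one
#' phenotype table per requested trait, with seeds drawn from named
#' substreams of \code{seed}.
#'
#' @param n_per_line,n_snps,n_chromosomes,map_length_cm,divergence passed to
#'   \code{\link{simulate_founders}}.
#' @param n_f1,n_sires_f1,n_f2,n_hatches passed to
#'   \code{\link{make_cross_design}}.
#' @param traits named list of \code{trait_architecture}s
#'   (default \code{chicken_traits()}).
#' @param seed root seed.
#' @return a \code{sim_population} with an added \code{phenotypes} element
#'   (named list of phenotype tables).
#' @export
simulate_population <- function(n_per_line = 10, n_snps = 5000,
                                n_chromosomes = 10, map_length_cm = 100,
                                divergence = 0.3,
                                n_f1 = 51, n_sires_f1 = 8, n_f2 = 511,
                                n_hatches = 4,
                                traits = chicken_traits(), seed = 1) {
  fnd <- simulate_founders(n_per_line, n_snps, n_chromosomes, map_length_cm,
                           divergence, seed = substream_seed(seed, "founders"))
  pop <- make_cross_design(fnd, n_f1, n_sires_f1, n_f2, n_hatches,
                           seed = substream_seed(seed, "cross"))
  pop$phenotypes <- lapply(traits, function(a) {
    simulate_phenotypes(pop, a,
                        seed = substream_seed(seed, paste0("trait_", a$name)))
  })
  pop
}
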