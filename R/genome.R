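#' Build a miniature genome model
#'
#' Constructs a scaled-down genome with named chromosomes, p/q arm boundaries
#' and genes tiled along each arm. The default is a 22-chromosome genome at
#' roughly 1/1000 of real chromosome lengths with 25 genes per arm
#' (about 1,100 genes), which keeps arm-level copy-number semantics
#' (e.g. "fraction of 3p lost") while staying fast to simulate.
#'
#' @param n_chromosomes number of autosomes to generate (>= 3, so that a
#'   chromosome named "3" with a p arm exists).
#' @param genes_per_arm genes tiled on each arm (>= 1).
#' @param scale multiplier applied to human-like chromosome lengths.
#' @param seed integer seed; the model is a pure function of the arguments.
#' @return an object of class \code{genome_model}: a list with data frames
#'   \code{chromosomes} (chrom, length), \code{arms} (chrom, arm, start, end)
#'   and \code{genes} (gene, chrom, start, end); coordinates are 1-based
#'   inclusive.
#' @export
make_genome <- function(n_chromosomes = 22, genes_per_arm = 25,
                        scale = 0.001, seed = 1) {
  if (n_chromosomes < 3) stop("n_chromosomes must be >= 3")
  if (genes_per_arm < 1) stop("genes_per_arm must be >= 1")
  if (scale <= 0) stop("scale must be positive")
  set.seed(as.integer(seed))

  # loosely decreasing human-like lengths with mild jitter
  base <- seq(245e6, 55e6, length.out = n_chromosomes)
  len <- round(base * scale * stats::runif(n_chromosomes, 0.95, 1.05))
  chrom <- as.character(seq_len(n_chromosomes))
  centro <- round(len * stats::runif(n_chromosomes, 0.3, 0.6))
  centro <- pmin(pmax(centro, 2L), len - 2L)  # strictly inside

  arms <- do.call(rbind, lapply(seq_len(n_chromosomes), function(i) {
    data.frame(chrom = chrom[i], arm = c("p", "q"),
               start = c(1, centro[i] + 1),
               end = c(centro[i], len[i]),
               stringsAsFactors = FALSE)
  }))
  arms$arm_id <- paste0(arms$chrom, arms$arm)

  genes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(j) {
    a <- arms[j, ]
    slot <- (a$end - a$start + 1) %/% genes_per_arm
    k <- seq_len(genes_per_arm)
    pad <- max(1L, ceiling(slot * 0.1))
    gs <- a$start + (k - 1L) * slot + pad
    ge <- a$start + k * slot - pad - 1L
    ge <- pmax(ge, gs)  # non-degenerate even for tiny slots
    data.frame(gene = sprintf("G%s_%02d", a$arm_id, k),
               chrom = a$chrom, start = gs, end = ge,
               stringsAsFactors = FALSE)
  }))

  gm <- structure(list(
    chromosomes = data.frame(chrom = chrom, length = len,
                             stringsAsFactors = FALSE),
    arms = arms[, c("arm_id", "chrom", "arm", "start", "end")],
    genes = genes
  ), class = "genome_model")
  validate_genome(gm)
  gm
}

#' Validate a genome model's invariants
#'
#' Checks that arm boundaries lie strictly inside chromosomes, genes lie
#' within their chromosome, and gene intervals are non-degenerate.
#' @param genome a \code{genome_model}.
#' @return the genome, invisibly; errors on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  ch <- genome$chromosomes
  if (anyDuplicated(ch$chrom)) stop("duplicate chromosome names")
  a <- merge(genome$arms, ch, by = "chrom")
  if (any(a$start < 1 | a$end > a$length)) stop("arm outside chromosome")
  p <- a[a$arm == "p", ]
  if (any(p$end >= p$length - 1 | p$end < 1)) {
    stop("centromere not strictly inside chromosome")
  }
  g <- merge(genome$genes, ch, by = "chrom")
  if (any(g$start < 1 | g$end > g$length)) stop("gene outside chromosome")
  if (any(g$start > g$end)) stop("degenerate gene interval")
  if (anyDuplicated(genome$genes$gene)) stop("duplicate gene ids")
  invisible(genome)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %d genes, total %.0f bp\n",
              nrow(x$chromosomes), nrow(x$genes), sum(x$chromosomes$length)))
  invisible(x)
}

# Resolve an event target ("3p", "14") to intervals (chrom, start, end).
# Whole-chromosome targets cover both arms. Errors on unknown targets.
resolve_target <- function(genome, target) {
  if (target %in% genome$arms$arm_id) {
    a <- genome$arms[genome$arms$arm_id == target, ]
    return(data.frame(chrom = a$chrom, start = a$start, end = a$end,
                      stringsAsFactors = FALSE))
  }
  if (target %in% genome$chromosomes$chrom) {
    c0 <- genome$chromosomes[genome$chromosomes$chrom == target, ]
    return(data.frame(chrom = c0$chrom, start = 1, end = c0$length,
                      stringsAsFactors = FALSE))
  }
  stop(sprintf("unknown arm or chromosome: '%s'", target))
}

#' Default RCC subtype archetypes
#'
#' Arm-level copy-number archetypes for the three common renal cell
#' carcinoma subtypes: clear cell (ccRCC; 3p loss plus 5q/8q gains and
#' chromosome 14 loss), papillary (pRCC; gains of chromosomes 7, 16 and 17
#' with occasional 9p loss) and chromophobe (chRCC; single-copy losses of
#' chromosomes 1, 2, 6, 10, 13 and 17). Event magnitudes are in log2 units;
#' the first event of each archetype is its defining lesion.
#'
#' @param genome a \code{genome_model}; archetype events and mutation-rate
#'   genes are restricted to targets present in it.
#' @return named list of archetype objects, each a list with \code{name},
#'   \code{events} (target, direction, penetrance, magnitude),
#'   \code{focal_event_rate} and \code{mutation_rates}.
#' @export
default_archetypes <- function(genome) {
  mk <- function(name, target, direction, penetrance, magnitude,
                 focal_rate, mut_genes, mut_rates) {
    ev <- data.frame(target = target, direction = direction,
                     penetrance = penetrance, magnitude = magnitude,
                     stringsAsFactors = FALSE)
    keep <- vapply(ev$target, function(t) {
      t %in% genome$arms$arm_id || t %in% genome$chromosomes$chrom
    }, logical(1))
    ev <- ev[keep, , drop = FALSE]
    mu <- stats::setNames(mut_rates, mut_genes)
    mu <- mu[names(mu) %in% genome$genes$gene]
    validate_archetype(list(name = name, events = ev,
                            focal_event_rate = focal_rate,
                            mutation_rates = mu), genome)
  }
  list(
    ccRCC = mk("ccRCC",
               target = c("3p", "5q", "14", "8q", "6q", "9p", "1p"),
               direction = c("loss", "gain", "loss", "gain", "loss", "loss",
                             "loss"),
               penetrance = c(0.9, 0.7, 0.5, 0.35, 0.35, 0.35, 0.25),
               magnitude = c(-0.5, 0.5, -0.5, 0.5, -0.5, -0.5, -0.5),
               focal_rate = 2,
               mut_genes = c("G3p_01", "G3p_02", "G3p_03"),
               mut_rates = c(0.65, 0.35, 0.15)),
    pRCC = mk("pRCC",
              target = c("7", "17", "16", "12", "20", "3", "8", "9p"),
              direction = c("gain", "gain", "gain", "gain", "gain", "gain",
                            "gain", "loss"),
              penetrance = c(0.9, 0.85, 0.6, 0.5, 0.45, 0.3, 0.25, 0.3),
              magnitude = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, -0.5),
              focal_rate = 2,
              mut_genes = c("G7q_01", "G16q_01"),
              mut_rates = c(0.5, 0.2)),
    chRCC = mk("chRCC",
               target = c("1", "2", "6", "10", "13", "17"),
               direction = rep("loss", 6),
               penetrance = rep(0.9, 6),
               magnitude = rep(-0.5, 6),
               focal_rate = 1,
               mut_genes = c("G17p_01", "G17p_02"),
               mut_rates = c(0.6, 0.2))
  )
}

#' Validate a subtype archetype
#' @param arch archetype list (name, events, focal_event_rate, mutation_rates).
#' @param genome genome the events must refer to.
#' @return the archetype, invisibly usable; errors on violation.
#' @export
validate_archetype <- function(arch, genome) {
  ev <- arch$events
  if (!all(ev$penetrance >= 0 & ev$penetrance <= 1)) {
    stop("penetrance must be in [0,1]")
  }
  if (!all(is.finite(ev$magnitude))) stop("magnitude must be finite")
  if (!all(ev$direction %in% c("gain", "loss"))) {
    stop("direction must be 'gain' or 'loss'")
  }
  if (arch$focal_event_rate < 0) stop("focal_event_rate must be >= 0")
  for (t in ev$target) resolve_target(genome, t)
  if (length(arch$mutation_rates)) {
    if (!all(arch$mutation_rates >= 0 & arch$mutation_rates <= 1)) {
      stop("mutation rates must be in [0,1]")
    }
    bad <- setdiff(names(arch$mutation_rates), genome$genes$gene)
    if (length(bad)) stop("mutation rate for unknown gene: ", bad[1])
  }
  invisible(arch)
}

# Deterministic 31-bit string hash used to split RNG streams per sample,
# so generated profiles do not depend on group ordering.
hash_seed <- function(key, seed) {
  v <- utf8ToInt(key)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}
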