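#' Simulate a gel-shift titration curve
#'
#' Generates fraction-bound data from the Hill equation plus additive
#' Gaussian noise, clipped to `[0, 1]`. The default grid is 12
#' log-spaced protein concentrations from 20 nM to 2 uM, matching the
#' direct-titration design (trace RNA, protein spanning both sides of
#' half-saturation). Identical seeds give identical curves.
#'
#' @param kd True dissociation constant, nM.
#' @param n True Hill coefficient.
#' @param conc_nM Concentration grid, nM (strictly positive,
#'   increasing).
#' @param noise_sd Additive Gaussian noise SD on the fraction (>= 0).
#' @param trace_rna_nM Trace RNA concentration (metadata only).
#' @param seed Random seed; `NULL` leaves the RNG state alone.
#' @return A tibble (`conc_nM`, `fraction_bound`) with attribute
#'   `truth` = `list(kd, n, noise_sd)`.
#' @examples
#' sim_binding_curve(kd = 460, n = 2.8, seed = 1)
#' @export
sim_binding_curve <- function(kd = 460, n = 2.8,
                              conc_nM = exp(seq(log(20), log(2000),
                                                length.out = 12)),
                              noise_sd = 0.03, trace_rna_nM = 26,
                              seed = NULL) {
  if (any(conc_nM <= 0)) rlang::abort("Concentrations must be > 0.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  y <- hill_fraction(conc_nM, kd, n)
  if (noise_sd > 0) {
    y <- pmin(pmax(y + stats::rnorm(length(y), sd = noise_sd), 0), 1)
  }
  out <- tibble::tibble(conc_nM = conc_nM, fraction_bound = y)
  attr(out, "truth") <- list(kd = kd, n = n, noise_sd = noise_sd,
                             trace_rna_nM = trace_rna_nM)
  out
}

#' Simulate an ITC thermogram
#'
#' Per-injection heats from [itc_predicted_heats()] plus proportional
#' and additive Gaussian noise. With `blank = TRUE` a constant
#' titrant-into-buffer dilution heat is added to the signal channel and
#' returned alongside, so blank subtraction recovers the binding signal.
#'
#' @param kd_nM,dh_kcal,n True independent-binding-model parameters.
#' @param protocol An [itc_protocol()].
#' @param noise_prop Proportional noise SD (fraction of each heat).
#' @param noise_ucal Additive noise SD, ucal.
#' @param blank Generate a blank (dilution-heat) channel?
#' @param blank_ucal Constant dilution heat per injection, ucal.
#' @param seed Random seed.
#' @return A tibble (`injection`, `dV_ul`, `heat_ucal`, and
#'   `blank_ucal` if requested) with attribute `truth`.
#' @examples
#' sim_itc_thermogram(kd_nM = 735, dh_kcal = -2, n = 0.52, seed = 1)
#' @export
sim_itc_thermogram <- function(kd_nM = 735, dh_kcal = -2, n = 0.52,
                               protocol = itc_protocol(),
                               noise_prop = 0.02, noise_ucal = 0.1,
                               blank = FALSE, blank_ucal = -0.15,
                               seed = NULL) {
  if (noise_prop < 0 || noise_ucal < 0) {
    rlang::abort("Noise scales must be >= 0.")
  }
  if (!is.null(seed)) set.seed(seed)
  pred <- itc_predicted_heats(protocol, kd_nM, dh_kcal, n)
  q <- pred$heat_ucal
  n_inj <- length(q)
  noisy <- q * (1 + stats::rnorm(n_inj, sd = noise_prop)) +
    stats::rnorm(n_inj, sd = noise_ucal)
  out <- tibble::tibble(injection = pred$injection, dV_ul = pred$dV_ul,
                        heat_ucal = noisy)
  if (blank) {
    out$heat_ucal <- out$heat_ucal + blank_ucal
    out$blank_ucal <- rep(blank_ucal, n_inj)
  }
  attr(out, "truth") <- list(kd_nM = kd_nM, dh_kcal = dh_kcal, n = n,
                             noise_prop = noise_prop,
                             noise_ucal = noise_ucal,
                             noiseless = q)
  out
}

# Pixel-exact ellipse rasterisation: centre (cx, cy) in (col, row)
# pixel coordinates, semi-axes (a, b) in pixels, rotation in radians.
rasterize_ellipse <- function(nr, nc, cx, cy, a, b, angle = 0) {
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  dx <- cols - cx
  dy <- rows - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Simulate a bright-field droplet image with ground truth
#'
#' Builds a Gaussian-noise background and subtracts a fixed depth inside
#' each rasterised ellipse (droplets are darker than their
#' surroundings). The exact pixel mask of each object and its true
#' shape measurements are returned as ground truth, so segmentation
#' accuracy can be scored pixel for pixel.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size_um Pixel calibration, um per pixel.
#' @param ellipses Data frame with columns `cx`, `cy` (pixel centre,
#'   column/row), `a`, `b` (semi-axes, pixels), `angle` (radians) and
#'   `depth` (intensity drop, > 0). Ellipses overflowing the frame are
#'   clipped and flagged.
#' @param background_mean,background_sd Background intensity model.
#' @param bit_depth Camera bit depth; intensities are clipped into
#'   range (with a warning if the depth pushes pixels below 0).
#' @param seed Random seed.
#' @return A [brightfield_image()] with attributes `truth_mask`
#'   (logical matrix), `truth` (per-object tibble: pixel count, true
#'   eccentricity, equivalent diameter in um, clipped flag) and
#'   `truth_coverage` (percent of pixels inside objects).
#' @examples
#' ell <- data.frame(cx = 100, cy = 100, a = 20, b = 20,
#'                   angle = 0, depth = 600)
#' img <- sim_droplet_image(ellipses = ell, seed = 1)
#' attr(img, "truth_coverage")
#' @export
sim_droplet_image <- function(width = 500, height = 500,
                              pixel_size_um = 0.5,
                              ellipses = NULL,
                              background_mean = 2000,
                              background_sd = 0,
                              bit_depth = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- height; nc <- width
  px <- matrix(background_mean, nr, nc)
  if (background_sd > 0) {
    px <- px + matrix(stats::rnorm(nr * nc, sd = background_sd), nr, nc)
  }
  truth_mask <- matrix(FALSE, nr, nc)
  objects <- list()
  if (!is.null(ellipses) && nrow(ellipses) > 0) {
    stopifnot(all(c("cx", "cy", "a", "b", "depth") %in% names(ellipses)))
    if (any(ellipses$depth <= 0)) {
      rlang::abort("`depth` must be > 0 (droplets are darker than background).")
    }
    if (!"angle" %in% names(ellipses)) ellipses$angle <- 0
    for (i in seq_len(nrow(ellipses))) {
      e <- ellipses[i, ]
      m <- rasterize_ellipse(nr, nc, e$cx, e$cy, e$a, e$b, e$angle)
      clipped <- e$cx - e$a < 0.5 || e$cx + e$a > nc + 0.5 ||
        e$cy - e$b < 0.5 || e$cy + e$b > nr + 0.5
      px[m] <- px[m] - e$depth
      truth_mask <- truth_mask | m
      ab <- sort(c(e$a, e$b), decreasing = TRUE)
      objects[[i]] <- tibble::tibble(
        object = i,
        n_pixels = sum(m),
        eccentricity_true = sqrt(1 - (ab[2] / ab[1])^2),
        equiv_diameter_um = 2 * sqrt(sum(m) * pixel_size_um^2 / pi),
        clipped = clipped
      )
    }
  }
  maxv <- 2^bit_depth - 1
  if (any(px < 0)) {
    rlang::warn("Object depth pushed intensities below 0; clipping.")
  }
  px <- pmin(pmax(px, 0), maxv)
  img <- brightfield_image(round(px), pixel_size_um, bit_depth)
  attr(img, "truth_mask") <- truth_mask
  attr(img, "truth") <- if (length(objects) > 0) {
    dplyr::bind_rows(objects)
  } else {
    tibble::tibble(object = integer(0), n_pixels = integer(0),
                   eccentricity_true = numeric(0),
                   equiv_diameter_um = numeric(0), clipped = logical(0))
  }
  attr(img, "truth_coverage") <- 100 * sum(truth_mask) / (nr * nc)
  img
}

.default_category_lengths <- c(
  exon = 30000, intron = 40000, lincRNA = 5000, snRNA = 1000,
  rRNA = 2000, miRNA = 500, tRNA = 1520, intergenic = 19980
)

random_barcodes <- function(n, len = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a PAR-iCLIP dataset on a toy annotated genome
#'
#' Lays the eight genomic categories out contiguously on one toy
#' chromosome, subdivides the tRNA region into cloverleaf gene models,
#' and draws reads multinomially with category probability proportional
#' to genome fraction times the enrichment vector. Within tRNA genes the
#' cross-link position is drawn per structural-element bias (default:
#' anticodon loop 0.70, T-loop 0.15, D-loop 0.10, elsewhere 0.05 —
#' the qualitative anticodon-loop preference of truncation-based tau
#' CLIP). Reads are laid down + strand with the cross-link site
#' immediately 5' of the read start. PCR duplicates and sub-threshold
#' (short or low-score) decoys can be injected at configurable rates
#' for filter testing; the truth record names them.
#'
#' The expected fold enrichment of category c is
#' `enrichment[c] / sum(genome_fraction * enrichment)`; the truth
#' record reports these normalised folds.
#'
#' @param category_lengths Named vector of category nucleotide totals
#'   (must include tRNA; intergenic is laid out like the others).
#' @param enrichment Named non-negative vector of per-category
#'   enrichment weights (default all 1: the null model).
#' @param n_reads Number of genuine reads to draw.
#' @param crosslink_bias Named weights for anticodon loop, T-loop,
#'   D-loop and everything else, used inside tRNA genes.
#' @param read_length Range (min, max) of read lengths.
#' @param dup_rate Fraction of reads duplicated (PCR decoys).
#' @param subthreshold_rate Fraction of extra reads that violate the
#'   length or score filters.
#' @param trna_gene_length Length of each toy tRNA gene, nt.
#' @param seed Random seed.
#' @return A list: `reads` (tibble), `annotation`
#'   ([genome_annotation()]), `trna_models` (list of [trna_model()]),
#'   `truth` (list: planted folds, per-read category, duplicate and
#'   decoy read names, cross-link element per tRNA read).
#' @examples
#' sim <- sim_clip_dataset(n_reads = 1000, seed = 42)
#' names(sim)
#' @export
sim_clip_dataset <- function(category_lengths = .default_category_lengths,
                             enrichment = NULL, n_reads = 10000,
                             crosslink_bias = c(anticodon_loop = 0.70,
                                                t_loop = 0.15,
                                                d_loop = 0.10,
                                                other = 0.05),
                             read_length = c(25, 40), dup_rate = 0,
                             subthreshold_rate = 0,
                             trna_gene_length = 76, seed = NULL) {
  stopifnot(all(category_lengths > 0), "tRNA" %in% names(category_lengths))
  if (is.null(enrichment)) {
    enrichment <- stats::setNames(rep(1, length(category_lengths)),
                                  names(category_lengths))
  }
  enrichment <- enrichment[names(category_lengths)]
  if (anyNA(enrichment) || any(enrichment < 0)) {
    rlang::abort("`enrichment` must be non-negative and name every category.")
  }
  if (!is.null(seed)) set.seed(seed)
  cats <- names(category_lengths)
  ends <- cumsum(category_lengths)
  starts <- c(0, head(ends, -1))
  names(starts) <- names(ends) <- cats
  chrom_len <- sum(category_lengths)
  iv <- tibble::tibble(chrom = "chrT", start = unname(starts),
                       end = unname(ends), category = cats)
  annotation <- genome_annotation(
    iv[iv$category != "intergenic", , drop = FALSE],
    c(chrT = chrom_len)
  )
  # tRNA genes tile the tRNA region
  n_genes <- floor(category_lengths[["tRNA"]] / trna_gene_length)
  stopifnot(n_genes >= 1)
  models <- lapply(seq_len(n_genes), function(i) {
    g_start <- starts[["tRNA"]] + (i - 1) * trna_gene_length
    trna_model(sprintf("tRNA-toy-%d", i), "chrT", g_start,
               g_start + trna_gene_length, "+",
               anticodon_start = 34)
  })
  genome_frac <- category_lengths / chrom_len
  p <- genome_frac * enrichment
  if (sum(p) <= 0) rlang::abort("Total sampling probability is zero.")
  planted_folds <- enrichment / sum(p)
  p <- p / sum(p)
  read_cat <- sample(cats, n_reads, replace = TRUE, prob = p)
  # cross-link site per read (0-based genomic position)
  site <- integer(n_reads)
  element <- rep(NA_character_, n_reads)
  is_trna <- read_cat == "tRNA"
  n_t <- sum(is_trna)
  if (any(!is_trna)) {
    k <- sum(!is_trna)
    cs <- starts[read_cat[!is_trna]]
    cl <- category_lengths[read_cat[!is_trna]]
    site[!is_trna] <- cs + floor(stats::runif(k) * cl)
  }
  if (n_t > 0) {
    gene_i <- sample(n_genes, n_t, replace = TRUE)
    el <- models[[1]]$elements
    w <- rep(crosslink_bias[["other"]] / sum(!el %in%
               c("anticodon_loop", "t_loop", "d_loop")), length(el))
    for (nm in c("anticodon_loop", "t_loop", "d_loop")) {
      w[el == nm] <- crosslink_bias[[nm]] / sum(el == nm)
    }
    pos_gene <- sample(length(el), n_t, replace = TRUE, prob = w)
    site[is_trna] <- vapply(seq_len(n_t), function(j) {
      models[[gene_i[j]]]$start + pos_gene[j] - 1L
    }, numeric(1))
    element[is_trna] <- el[pos_gene]
  }
  len <- sample(seq(read_length[1], read_length[2]), n_reads, replace = TRUE)
  site <- pmin(site, chrom_len - 2)  # keep at least a 1-nt read in bounds
  start <- site + 1          # truncation: site is immediately 5' of start
  end <- pmin(start + len, chrom_len)
  reads <- tibble::tibble(
    chrom = "chrT", start = start, end = end,
    name = sprintf("read%06d", seq_len(n_reads)),
    score = sample(10:42, n_reads, replace = TRUE),
    strand = "+",
    random_barcode = random_barcodes(n_reads),
    sample_barcode = "SMP1"
  )
  dup_names <- character(0)
  if (dup_rate > 0) {
    n_dup <- round(dup_rate * n_reads)
    src <- sample(n_reads, n_dup, replace = TRUE)
    dups <- reads[src, ]
    # suffixed names sort after their source read, so deduplication
    # deterministically retains the original
    dups$name <- sprintf("%s.dup%d", reads$name[src], seq_len(n_dup))
    dup_names <- dups$name
    reads <- dplyr::bind_rows(reads, dups)
  }
  decoy_names <- character(0)
  if (subthreshold_rate > 0) {
    n_decoy <- round(subthreshold_rate * n_reads)
    pos <- floor(stats::runif(n_decoy) * (chrom_len - 60))
    short <- stats::runif(n_decoy) < 0.5
    decoys <- tibble::tibble(
      chrom = "chrT", start = pos,
      end = pos + ifelse(short, 15, 30),
      name = sprintf("decoy%06d", seq_len(n_decoy)),
      score = ifelse(short, sample(10:42, n_decoy, replace = TRUE),
                     sample(0:9, n_decoy, replace = TRUE)),
      strand = "+",
      random_barcode = random_barcodes(n_decoy),
      sample_barcode = "SMP1"
    )
    decoy_names <- decoys$name
    reads <- dplyr::bind_rows(reads, decoys)
  }
  reads <- reads[sample(nrow(reads)), ]
  list(
    reads = reads,
    annotation = annotation,
    trna_models = models,
    truth = list(
      planted_folds = planted_folds,
      genome_fraction = genome_frac,
      read_category = stats::setNames(read_cat,
                                      sprintf("read%06d", seq_len(n_reads))),
      crosslink_element = element,
      duplicate_names = dup_names,
      decoy_names = decoy_names,
      crosslink_bias = crosslink_bias
    )
  )
}

#' Ground-truth record of a simulated dataset
#'
#' Convenience accessor for the `truth` attribute every generator
#' attaches to its output.
#'
#' @param x A simulated object (tibble or image).
#' @return The truth record (a list), or `NULL` if absent.
#' @export
sim_truth <- function(x) attr(x, "truth", exact = TRUE)
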