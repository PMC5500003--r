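#' Genome annotation for category enrichment
#'
#' Bundles category-labelled intervals (0-based half-open, BED-style)
#' with chromosome lengths. The eight categories used for read
#' classification are exon, intron, lincRNA, snRNA, rRNA, miRNA, tRNA
#' and intergenic; intergenic is implicit (the complement of all other
#' categories) and need not be supplied.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`,
#'   `category` (and optionally `strand`, `name`).
#' @param chrom_lengths Named numeric vector of chromosome lengths, or a
#'   data frame with columns `chrom`, `length`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(intervals, chrom_lengths) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "category") %in% names(intervals)))
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  if (any(intervals$start < 0) || any(intervals$end <= intervals$start)) {
    rlang::abort("Intervals must satisfy 0 <= start < end.")
  }
  len <- chrom_lengths[intervals$chrom]
  if (anyNA(len) || any(intervals$end > len)) {
    rlang::abort("Intervals must lie within their chromosome bounds.")
  }
  structure(
    list(intervals = tibble::as_tibble(intervals),
         chrom_lengths = chrom_lengths),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d intervals, %d chromosomes (%.0f nt)\n",
              nrow(x$intervals), length(x$chrom_lengths),
              sum(x$chrom_lengths)))
  invisible(x)
}

# BED-style tibble -> GRanges (0-based half-open -> 1-based closed)
as_granges <- function(df, use_strand = TRUE) {
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
}

#' Read CLIP alignment records from a BED-like TSV
#'
#' Expects the columns `chrom`, `start`, `end`, `name`, `score`,
#' `strand`, `random_barcode`, `sample_barcode` (tab-separated, with a
#' header). Coordinates are 0-based half-open.
#'
#' @param path Path to the TSV file.
#' @return A tibble of aligned reads.
#' @export
read_clip_reads <- function(path) {
  data <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "start", "end", "name", "score", "strand",
            "random_barcode", "sample_barcode")
  if (!all(need %in% names(data))) {
    rlang::abort(paste("Missing columns:",
                       paste(setdiff(need, names(data)), collapse = ", ")))
  }
  validate_reads(data)
  tibble::as_tibble(data)
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (any(reads$start >= reads$end)) rlang::abort("Reads must have start < end.")
  if (!all(reads$strand %in% c("+", "-"))) {
    rlang::abort("Strand must be '+' or '-'.")
  }
  invisible(reads)
}

#' Deduplicate and filter aligned CLIP reads
#'
#' Applies the standard iCLIP preprocessing: PCR duplicates (identical
#' chromosome, start, strand and random barcode) are collapsed to one
#' read; reads shorter than `min_length` (18 bp) or with alignment
#' score below `min_score` (10) are removed. The result is independent
#' of input order, and the operation is idempotent. Reads with a
#' missing random barcode are not silently dropped: they are returned
#' in the `unbarcoded` attribute.
#'
#' @param reads Read tibble (see [read_clip_reads()] for columns).
#' @param min_length Minimum read length kept (bp).
#' @param min_score Minimum alignment score kept.
#' @return Filtered, deduplicated read tibble (attribute `unbarcoded`
#'   holds barcode-less reads; attribute `n_removed` a named count
#'   breakdown).
#' @examples
#' reads <- sim_clip_dataset(n_reads = 100, seed = 1)$reads
#' nrow(preprocess_reads(reads))
#' @export
preprocess_reads <- function(reads, min_length = 18, min_score = 10) {
  validate_reads(reads)
  reads <- tibble::as_tibble(reads)
  if (!"random_barcode" %in% names(reads)) reads$random_barcode <- NA_character_
  no_bc <- is.na(reads$random_barcode) | reads$random_barcode == ""
  unbarcoded <- reads[no_bc, , drop = FALSE]
  kept <- reads[!no_bc, , drop = FALSE]
  n0 <- nrow(kept)
  sort_cols <- intersect(c("chrom", "start", "end", "strand",
                           "random_barcode", "name"), names(kept))
  kept <- kept %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(sort_cols))) %>%
    dplyr::distinct(.data$chrom, .data$start, .data$strand,
                    .data$random_barcode, .keep_all = TRUE)
  n_dup <- n0 - nrow(kept)
  len_ok <- (kept$end - kept$start) >= min_length
  score_ok <- if ("score" %in% names(kept)) kept$score >= min_score else TRUE
  out <- kept[len_ok & score_ok, , drop = FALSE]
  attr(out, "unbarcoded") <- unbarcoded
  attr(out, "n_removed") <- c(
    duplicates = n_dup,
    short = sum(!len_ok),
    low_score = sum(len_ok & !score_ok)
  )
  out
}

#' Call cross-link sites from read 5' truncation positions
#'
#' In truncation-based iCLIP, reverse transcription stops at the
#' nucleotide cross-linked to the protein, so the cross-link site is
#' the nucleotide immediately 5' of the read's 5' end in transcript
#' orientation: position `start - 1` for + strand reads and position
#' `end` for - strand reads (0-based). The alternative convention
#' `"read_start"` takes the read's first nucleotide itself. Identical
#' sites are aggregated with a supporting read count. Sites falling
#' before the chromosome start are clamped to 0 and flagged.
#'
#' @param reads Read tibble (ideally from [preprocess_reads()]).
#' @param convention `"truncation"` (default) or `"read_start"`.
#' @return A tibble: `chrom`, `position` (0-based), `strand`, `count`,
#'   `clamped`.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 100, end = 135,
#'                         strand = "+")
#' crosslink_sites(reads)$position # 99
#' @export
crosslink_sites <- function(reads, convention = c("truncation", "read_start")) {
  convention <- match.arg(convention)
  validate_reads(reads)
  pos <- if (convention == "truncation") {
    ifelse(reads$strand == "+", reads$start - 1, reads$end)
  } else {
    ifelse(reads$strand == "+", reads$start, reads$end - 1)
  }
  clamped <- pos < 0
  pos[clamped] <- 0
  tibble::tibble(chrom = reads$chrom, position = pos,
                 strand = reads$strand, clamped = clamped) %>%
    dplyr::group_by(.data$chrom, .data$position, .data$strand) %>%
    dplyr::summarise(count = dplyr::n(), clamped = any(.data$clamped),
                     .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$position)
}

.category_precedence <- c("tRNA", "rRNA", "miRNA", "snRNA", "lincRNA",
                          "exon", "intron", "intergenic")

# Resolve overlapping category annotations into a disjoint partition of
# the genome, by precedence; returns per-category nucleotide totals.
category_genome_nt <- function(annotation, precedence = .category_precedence) {
  iv <- annotation$intervals
  total <- sum(annotation$chrom_lengths)
  claimed <- GenomicRanges::GRanges()
  nt <- stats::setNames(numeric(length(precedence)), precedence)
  for (cat in setdiff(precedence, "intergenic")) {
    gr <- as_granges(iv[iv$category == cat, , drop = FALSE], use_strand = FALSE)
    gr <- GenomicRanges::reduce(gr)
    free <- GenomicRanges::setdiff(gr, claimed, ignore.strand = TRUE)
    nt[cat] <- sum(IRanges::width(free))
    claimed <- GenomicRanges::reduce(c(claimed, free))
  }
  nt["intergenic"] <- total - sum(IRanges::width(claimed))
  nt
}

#' Category enrichment of CLIP cross-link sites
#'
#' Assigns each read's cross-link site to exactly one genomic category
#' under a fixed precedence (default: tRNA > rRNA > miRNA > snRNA >
#' lincRNA > exon > intron > intergenic, so that small-RNA classes are
#' not swallowed by host exons/introns), then reports per category the
#' percentage of reads, the percentage of genomic nucleotides and the
#' fold enrichment = read% / genome%. Read percentages sum to 100.
#'
#' @param reads Read tibble (ideally from [preprocess_reads()]); set
#'   `by_site = FALSE` to assign by read midpoint instead of the
#'   cross-link site.
#' @param annotation A [genome_annotation()].
#' @param precedence Category precedence (first wins).
#' @param convention Cross-link site convention, see
#'   [crosslink_sites()].
#' @param by_site Assign by cross-link site (default) or read midpoint.
#' @return A tibble: `category`, `reads`, `read_pct`, `genome_pct`,
#'   `fold_enrichment` (with `infinite_enrichment` flagging categories
#'   that received reads but occupy no genomic nucleotides).
#' @examples
#' sim <- sim_clip_dataset(n_reads = 2000, seed = 1)
#' enrichment_table(sim$reads, sim$annotation)
#' @export
enrichment_table <- function(reads, annotation,
                             precedence = .category_precedence,
                             convention = "truncation",
                             by_site = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  validate_reads(reads)
  pos <- if (by_site) {
    s <- if (convention == "truncation") {
      ifelse(reads$strand == "+", reads$start - 1, reads$end)
    } else {
      ifelse(reads$strand == "+", reads$start, reads$end - 1)
    }
    pmax(s, 0)
  } else {
    floor((reads$start + reads$end - 1) / 2)
  }
  sites <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = pos + 1, width = 1)
  )
  assigned <- rep("intergenic", length(sites))
  iv <- annotation$intervals
  unclaimed <- rep(TRUE, length(sites))
  for (cat in setdiff(precedence, "intergenic")) {
    gr <- as_granges(iv[iv$category == cat, , drop = FALSE], use_strand = FALSE)
    if (length(gr) == 0) next
    hit <- IRanges::overlapsAny(sites, gr)
    assigned[unclaimed & hit] <- cat
    unclaimed <- unclaimed & !hit
  }
  nt <- category_genome_nt(annotation, precedence)
  counts <- table(factor(assigned, levels = precedence))
  out <- tibble::tibble(
    category = precedence,
    reads = as.integer(counts),
    read_pct = 100 * as.integer(counts) / length(sites),
    genome_pct = 100 * as.numeric(nt[precedence]) / sum(nt)
  )
  out$fold_enrichment <- ifelse(out$genome_pct > 0,
                                out$read_pct / out$genome_pct, NA_real_)
  out$infinite_enrichment <- out$genome_pct == 0 & out$reads > 0
  out
}

#' Cluster overlapping reads and retain well-supported clusters
#'
#' Reads on the same strand of the same chromosome that overlap by at
#' least one nucleotide merge transitively (single linkage) into
#' clusters; clusters supported by fewer than `min_reads` reads
#' (default 5) are discarded. The result is invariant under permutation
#' of the input.
#'
#' @param reads Read tibble.
#' @param min_reads Minimum reads per retained cluster.
#' @return A tibble: `chrom`, `start`, `end` (0-based half-open span),
#'   `strand`, `n_reads`, `members` (list column of read names, or row
#'   indices if no `name` column).
#' @examples
#' sim <- sim_clip_dataset(n_reads = 500, seed = 1)
#' cluster_reads(sim$reads)
#' @export
cluster_reads <- function(reads, min_reads = 5) {
  validate_reads(reads)
  reads <- tibble::as_tibble(reads)
  if (!"name" %in% names(reads)) {
    reads$name <- paste0("read", seq_len(nrow(reads)))
  }
  gr <- as_granges(reads)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  cl <- tibble::tibble(
    read = S4Vectors::queryHits(hits),
    cluster = S4Vectors::subjectHits(hits)
  ) %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::summarise(
      n_reads = dplyr::n(),
      members = list(sort(reads$name[.data$read])),
      .groups = "drop"
    )
  spans <- tibble::tibble(
    cluster = seq_along(merged),
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged),
    strand = as.character(GenomicRanges::strand(merged))
  )
  dplyr::left_join(spans, cl, by = "cluster") %>%
    dplyr::filter(.data$n_reads >= min_reads) %>%
    dplyr::arrange(.data$chrom, .data$start, .data$strand) %>%
    dplyr::select("chrom", "start", "end", "strand", "n_reads", "members")
}

#' Standard cloverleaf structural model of a tRNA gene
#'
#' Labels every position of a tRNA gene with its secondary-structure
#' element (acceptor stem, D-loop, anticodon stem, anticodon loop,
#' variable loop, T-loop) on a simplified 76-nt cloverleaf: positions
#' 1-7 and 66-76 acceptor stem, 8-25 D-arm, 26-31 and 39-43 anticodon
#' stem, 32-38 anticodon loop (anticodon at 34-36), 44-47 variable
#' loop, 48-65 T-arm. Shorter or longer genes scale the anticodon
#' position; the defaults suit the compact genes produced by
#' [sim_clip_dataset()].
#'
#' @param gene_id Gene identifier (must match the annotation interval
#'   `name`).
#' @param chrom,start,end,strand Genomic location of the gene (0-based
#'   half-open).
#' @param anticodon_start Position (1-based, within the gene) of the
#'   anticodon's first nucleotide; default 34.
#' @return An object of class `trna_model`: a list with the location,
#'   `length`, `anticodon` (triplet of gene positions) and `elements`
#'   (character vector labelling every position).
#' @export
trna_model <- function(gene_id, chrom, start, end, strand = "+",
                       anticodon_start = 34) {
  len <- end - start
  stopifnot(len > 0, anticodon_start >= 1, anticodon_start + 2 <= len)
  elements <- rep("acceptor_stem", len)
  seg <- function(from, to, label) {
    from <- max(1, from); to <- min(len, to)
    if (from <= to) elements[from:to] <<- label
  }
  seg(8, 25, "d_loop")
  seg(26, 31, "anticodon_stem")
  seg(32, 38, "anticodon_loop")
  seg(39, 43, "anticodon_stem")
  seg(44, 47, "variable_loop")
  seg(48, 65, "t_loop")
  anticodon <- anticodon_start:(anticodon_start + 2)
  if (!all(elements[anticodon] == "anticodon_loop")) {
    rlang::abort("The anticodon triplet must lie inside the anticodon loop.")
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, start = start, end = end,
         strand = strand, length = len, anticodon = anticodon,
         elements = elements),
    class = "trna_model"
  )
}

#' Anticodon-anchored positional profile of cross-link sites
#'
#' Re-indexes cross-link sites inside tRNA genes so that the first
#' anticodon nucleotide is position 1 (the anticodon spans positions
#' 1-3). Positions 5' of the anticodon run 0, -1, -2, ...; positions 3'
#' continue 4, 5, .... Sites outside every provided gene are routed to
#' an unassigned bin. The per-structural-element totals use each
#' model's element labels.
#'
#' @param sites Cross-link site tibble from [crosslink_sites()] (columns
#'   `chrom`, `position`, `strand`, `count`).
#' @param models List of [trna_model()] objects.
#' @return An object of class `positional_profile`: a tibble with
#'   columns `position` (anticodon-relative), `count` and `element`,
#'   with attributes `element_totals` (named vector) and `n_unassigned`.
#' @examples
#' sim <- sim_clip_dataset(n_reads = 2000, seed = 1)
#' pre <- preprocess_reads(sim$reads)
#' prof <- trna_positional_profile(crosslink_sites(pre), sim$trna_models)
#' head(prof)
#' @export
trna_positional_profile <- function(sites, models) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "position", "count") %in% names(sites)))
  if (length(models) == 0) rlang::abort("No tRNA models provided.")
  rows <- list()
  assigned <- rep(FALSE, nrow(sites))
  for (m in models) {
    stopifnot(inherits(m, "trna_model"))
    inside <- sites$chrom == m$chrom &
      sites$position >= m$start & sites$position < m$end
    if (!any(inside)) next
    assigned <- assigned | inside
    p_gene <- if (m$strand == "+") {
      sites$position[inside] - m$start + 1
    } else {
      m$end - sites$position[inside]
    }
    rel <- p_gene - m$anticodon[1] + 1
    rows[[length(rows) + 1]] <- tibble::tibble(
      position = rel,
      count = sites$count[inside],
      element = m$elements[p_gene]
    )
  }
  prof <- if (length(rows) == 0) {
    tibble::tibble(position = integer(0), count = integer(0),
                   element = character(0))
  } else {
    dplyr::bind_rows(rows) %>%
      dplyr::group_by(.data$position, .data$element) %>%
      dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
      dplyr::arrange(.data$position) %>%
      dplyr::select("position", "count", "element")
  }
  attr(prof, "element_totals") <-
    tapply(prof$count, prof$element, sum, default = 0)
  attr(prof, "n_unassigned") <- sum(sites$count[!assigned])
  class(prof) <- c("positional_profile", class(prof))
  prof
}

#' @export
autoplot.positional_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$count,
                                       fill = .data$element)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position relative to anticodon (anticodon = 1-3)",
                  y = "cross-link count", fill = "element") +
    ggplot2::theme_minimal()
}

#' Compare per-gene CLIP abundance against a background pool
#'
#' Normalises each pool to fractions, computes per-gene log2 ratios of
#' CLIP fraction to background fraction, and ranks genes by the ratio.
#' Genes absent from one pool receive a pseudocount (default 0.5 reads)
#' and are flagged `pseudocounted`.
#'
#' @param clip_counts Data frame with columns `gene`, `count` (CLIP
#'   reads per tRNA gene).
#' @param background_counts Same shape, for the background small-RNA
#'   pool.
#' @param pseudocount Reads substituted for missing genes.
#' @return A tibble: `gene`, `clip_count`, `background_count`,
#'   `clip_fraction`, `background_fraction`, `log2_ratio`, `rank`,
#'   `pseudocounted`.
#' @examples
#' abundance_compare(
#'   data.frame(gene = c("a", "b"), count = c(10, 90)),
#'   data.frame(gene = c("a", "b"), count = c(50, 50))
#' )
#' @export
abundance_compare <- function(clip_counts, background_counts,
                              pseudocount = 0.5) {
  for (d in list(clip_counts, background_counts)) {
    stopifnot(is.data.frame(d), all(c("gene", "count") %in% names(d)))
    if (nrow(d) == 0 || sum(d$count) <= 0) {
      rlang::abort("Each pool must contain at least one read.")
    }
  }
  joined <- dplyr::full_join(
    dplyr::rename(tibble::as_tibble(clip_counts), clip_count = "count"),
    dplyr::rename(tibble::as_tibble(background_counts),
                  background_count = "count"),
    by = "gene"
  )
  joined %>%
    dplyr::mutate(
      pseudocounted = is.na(.data$clip_count) | is.na(.data$background_count),
      clip_count = ifelse(is.na(.data$clip_count), pseudocount,
                          .data$clip_count),
      background_count = ifelse(is.na(.data$background_count), pseudocount,
                                .data$background_count),
      clip_fraction = .data$clip_count / sum(.data$clip_count),
      background_fraction =
        .data$background_count / sum(.data$background_count),
      log2_ratio = log2(.data$clip_fraction / .data$background_fraction)
    ) %>%
    dplyr::arrange(dplyr::desc(.data$log2_ratio)) %>%
    dplyr::mutate(rank = dplyr::row_number())
}

#' Read a category-annotated BED file
#'
#' BED with at least `chrom`, `start`, `end` and a category in the
#' fourth (name) column; no header.
#'
#' @param path Path to the BED file.
#' @param chrom_lengths As in [genome_annotation()].
#' @return A [genome_annotation()].
#' @export
read_bed_annotation <- function(path, chrom_lengths) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(bed) < 4) rlang::abort("BED file needs chrom, start, end, category.")
  names(bed)[1:4] <- c("chrom", "start", "end", "category")
  genome_annotation(bed[!is.na(bed$chrom), 1:4], chrom_lengths)
}
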