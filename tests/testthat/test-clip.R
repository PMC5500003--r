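make_reads <- function(...) {
  defaults <- list(chrom = "chrT", start = 100, end = 130, name = "r",
                   score = 30, strand = "+", random_barcode = "ACGTACGTA",
                   sample_barcode = "SMP1")
  args <- list(...)
  tibble::as_tibble(utils::modifyList(defaults, args))
}

test_that("PCR duplicates collapse on position plus random barcode", {
  reads <- dplyr::bind_rows(
    make_reads(name = c("a", "b", "c")),                        # 3 identical
    make_reads(name = "d", random_barcode = "TTTTTTTTT"),       # same pos, new bc
    make_reads(name = "e", start = 200, end = 230)              # new pos
  )
  out <- preprocess_reads(reads)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed")[["duplicates"]], 2)
})

test_that("length and score filters cut at the stated boundaries", {
  reads <- dplyr::bind_rows(
    make_reads(name = "len17", start = 100, end = 117,
               random_barcode = "AAAAAAAAA"),
    make_reads(name = "len18", start = 200, end = 218,
               random_barcode = "CCCCCCCCC"),
    make_reads(name = "score9", start = 300, end = 330, score = 9,
               random_barcode = "GGGGGGGGG"),
    make_reads(name = "score10", start = 400, end = 430, score = 10,
               random_barcode = "TTTTTTTTT")
  )
  out <- preprocess_reads(reads)
  expect_setequal(out$name, c("len18", "score10"))
})

test_that("preprocessing is idempotent and order-independent", {
  sim <- sim_clip_dataset(n_reads = 800, dup_rate = 0.3,
                          subthreshold_rate = 0.2, seed = 3)
  once <- preprocess_reads(sim$reads)
  twice <- preprocess_reads(once)
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  out2 <- preprocess_reads(shuffled)
  expect_equal(
    dplyr::arrange(as.data.frame(once), name),
    dplyr::arrange(as.data.frame(out2), name),
    ignore_attr = TRUE
  )
})

test_that("unbarcoded reads are binned, not dropped", {
  reads <- dplyr::bind_rows(
    make_reads(name = "ok"),
    make_reads(name = "nobc", start = 200, end = 230,
               random_barcode = NA_character_)
  )
  out <- preprocess_reads(reads)
  expect_equal(out$name, "ok")
  expect_equal(attr(out, "unbarcoded")$name, "nobc")
})

test_that("cross-link sites follow the truncation convention", {
  plus <- make_reads(start = 100, end = 135, strand = "+")
  minus <- make_reads(start = 100, end = 135, strand = "-")
  expect_equal(crosslink_sites(plus)$position, 99)
  expect_equal(crosslink_sites(minus)$position, 135)
  expect_equal(crosslink_sites(plus, convention = "read_start")$position, 100)
  # identical reads aggregate into one supported site
  two <- dplyr::bind_rows(
    make_reads(name = "a"),
    make_reads(name = "b", random_barcode = "TTTTTTTTT")
  )
  sites <- crosslink_sites(two)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$count, 2)
  # a read starting at 0 clamps its site and flags it
  edge <- crosslink_sites(make_reads(start = 0, end = 30))
  expect_true(edge$clamped)
  expect_equal(edge$position, 0)
})

test_that("read percentages sum to 100 and the null model gives fold ~ 1", {
  sim <- sim_clip_dataset(n_reads = 20000, seed = 21)
  et <- enrichment_table(preprocess_reads(sim$reads), sim$annotation)
  expect_equal(sum(et$read_pct), 100, tolerance = 1e-9)
  # every fold within 3 binomial standard errors of 1
  p <- et$genome_pct / 100
  se_fold <- sqrt(p * (1 - p) / sum(et$reads)) / p
  expect_true(all(abs(et$fold_enrichment - 1) <= 3 * se_fold))
})

test_that("a planted tRNA enrichment is recovered from the reads", {
  # genome with 1% tRNA; enrichment weights normalised so the planted
  # expected fold is exactly 50 (half of all reads from tRNA)
  lens <- c(exon = 30000, intron = 40000, lincRNA = 5000, snRNA = 1000,
            rRNA = 2000, miRNA = 500, tRNA = 988, intergenic = 19312)
  lens["intergenic"] <- 100000 - sum(lens[names(lens) != "intergenic"])
  g <- lens / sum(lens)
  enr <- stats::setNames(rep((1 - 50 * g[["tRNA"]]) / (1 - g[["tRNA"]]),
                             length(lens)), names(lens))
  enr["tRNA"] <- 50
  sim <- sim_clip_dataset(category_lengths = lens, enrichment = enr,
                          n_reads = 1e5, seed = 77)
  expect_equal(unname(sim$truth$planted_folds[["tRNA"]]), 50,
               tolerance = 1e-9)
  et <- enrichment_table(preprocess_reads(sim$reads), sim$annotation)
  fold <- et$fold_enrichment[et$category == "tRNA"]
  expect_lt(abs(fold - 50) / 50, 0.10)
})

test_that("toy genome with half its reads on 1% of nucleotides folds to 50", {
  # direct check of the fold definition, independent of the generator
  anno <- genome_annotation(
    tibble::tibble(chrom = "chrT", start = 0, end = 1000,
                   category = "tRNA"),
    c(chrT = 100000)
  )
  reads <- dplyr::bind_rows(
    make_reads(name = sprintf("t%03d", 1:50), start = 501, end = 531,
               random_barcode = sprintf("AAAAAA%03d", 1:50)),
    make_reads(name = sprintf("i%03d", 1:50), start = 50001, end = 50031,
               random_barcode = sprintf("CCCCCC%03d", 1:50))
  )
  et <- enrichment_table(reads, anno)
  expect_equal(et$fold_enrichment[et$category == "tRNA"], 50 / 1,
               tolerance = 1e-9)
  expect_equal(et$read_pct[et$category == "intergenic"], 50)
})

test_that("category precedence resolves overlapping annotations", {
  anno <- genome_annotation(
    tibble::tibble(chrom = "chrT",
                   start = c(0, 100), end = c(1000, 200),
                   category = c("exon", "tRNA")),
    c(chrT = 10000)
  )
  inside <- make_reads(start = 151, end = 181)   # site 150, inside both
  et <- enrichment_table(inside, anno)
  expect_equal(et$reads[et$category == "tRNA"], 1)
  expect_equal(et$reads[et$category == "exon"], 0)
  # genome nucleotides partition: exon loses the tRNA-claimed 100 nt
  expect_equal(et$genome_pct[et$category == "tRNA"], 100 * 100 / 10000)
  expect_equal(et$genome_pct[et$category == "exon"], 100 * 900 / 10000)
})

test_that("cluster retention cuts at exactly five supporting reads", {
  stack <- function(n, at, prefix) {
    make_reads(name = sprintf("%s%02d", prefix, seq_len(n)),
               start = at + seq_len(n), end = at + 40 + seq_len(n),
               random_barcode = sprintf("%s%08d", "A", seq_len(n)))
  }
  reads5 <- stack(5, 1000, "a")
  reads4 <- stack(4, 5000, "b")
  both <- dplyr::bind_rows(reads5, reads4)
  cl <- cluster_reads(both, min_reads = 5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_reads, 5)
  expect_equal(cl$start, 1001)
  # two separated stacks of five -> two clusters
  two <- dplyr::bind_rows(stack(5, 1000, "a"), stack(5, 9000, "c"))
  expect_equal(nrow(cluster_reads(two, 5)), 2)
  # permutation invariance
  cl2 <- cluster_reads(both[sample(nrow(both)), ], min_reads = 5)
  expect_equal(as.data.frame(cl), as.data.frame(cl2))
  # retained members never exceed the input read count
  expect_lte(sum(cl$n_reads), nrow(both))
})

test_that("opposite strands never merge into one cluster", {
  plus <- make_reads(name = sprintf("p%d", 1:5),
                     random_barcode = sprintf("A%08d", 1:5))
  minus <- make_reads(name = sprintf("m%d", 1:5), strand = "-",
                      random_barcode = sprintf("C%08d", 1:5))
  cl <- cluster_reads(dplyr::bind_rows(plus, minus), min_reads = 5)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$strand, c("+", "-"))
})

test_that("anticodon-relative indexing puts the anticodon at 1-3", {
  m <- trna_model("t1", "chrT", 1000, 1076, "+", anticodon_start = 34)
  site_at <- function(gene_pos) {
    tibble::tibble(chrom = "chrT", position = 1000 + gene_pos - 1,
                   strand = "+", count = 1L)
  }
  expect_equal(trna_positional_profile(site_at(34), list(m))$position, 1)
  expect_equal(trna_positional_profile(site_at(36), list(m))$position, 3)
  # one and two nucleotides 5' of the anticodon -> positions 0 and -1
  expect_equal(trna_positional_profile(site_at(33), list(m))$position, 0)
  expect_equal(trna_positional_profile(site_at(32), list(m))$position, -1)
  # sites outside every gene land in the unassigned bin
  off <- trna_positional_profile(
    tibble::tibble(chrom = "chrT", position = 5, strand = "+", count = 3L),
    list(m)
  )
  expect_equal(attr(off, "n_unassigned"), 3)
  expect_equal(nrow(off), 0)
})

test_that("profile total equals the number of profiled sites", {
  sim <- sim_clip_dataset(n_reads = 3000, seed = 12)
  sites <- crosslink_sites(preprocess_reads(sim$reads))
  prof <- trna_positional_profile(sites, sim$trna_models)
  in_genes <- sum(purrr::map_int(sim$trna_models, function(m) {
    sum(sites$count[sites$chrom == m$chrom & sites$position >= m$start &
                      sites$position < m$end])
  }))
  expect_equal(sum(prof$count), in_genes)
})

test_that("biased simulations put the profile mode in the anticodon loop", {
  sim <- sim_clip_dataset(n_reads = 40000, seed = 31)
  sites <- crosslink_sites(preprocess_reads(sim$reads))
  prof <- trna_positional_profile(sites, sim$trna_models)
  expect_gte(sum(prof$count), 500)
  mode_row <- prof[which.max(prof$count), ]
  expect_equal(mode_row$element, "anticodon_loop")
  tot <- attr(prof, "element_totals")
  expect_gt(tot[["anticodon_loop"]], tot[["t_loop"]])
  expect_gt(tot[["t_loop"]], tot[["d_loop"]])
})

test_that("abundance comparison computes log ratios and pseudocounts", {
  same <- abundance_compare(
    data.frame(gene = c("a", "b"), count = c(30, 70)),
    data.frame(gene = c("a", "b"), count = c(30, 70))
  )
  expect_equal(same$log2_ratio, c(0, 0))
  tenfold <- abundance_compare(
    data.frame(gene = c("a", "rest"), count = c(10, 90)),
    data.frame(gene = c("a", "rest"), count = c(1, 99))
  )
  expect_equal(tenfold$log2_ratio[tenfold$gene == "a"], log2(10),
               tolerance = 1e-12)
  disjoint <- abundance_compare(
    data.frame(gene = "a", count = 10),
    data.frame(gene = "b", count = 10)
  )
  expect_true(all(disjoint$pseudocounted))
  expect_error(
    abundance_compare(data.frame(gene = "a", count = 0),
                      data.frame(gene = "a", count = 1)),
    "at least one read"
  )
})

test_that("BED-like TSV round trip preserves reads and annotation", {
  sim <- sim_clip_dataset(n_reads = 200, seed = 8)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$reads, tsv)
  back <- read_clip_reads(tsv)
  expect_equal(nrow(back), 200)
  expect_equal(sort(back$name), sort(sim$reads$name))
  bed <- withr::local_tempfile(fileext = ".bed")
  iv <- sim$annotation$intervals
  readr::write_tsv(iv[, c("chrom", "start", "end", "category")], bed,
                   col_names = FALSE)
  anno <- read_bed_annotation(bed, c(chrT = 100000))
  expect_equal(nrow(anno$intervals), nrow(iv))
})
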