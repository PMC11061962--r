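#' Construct a genome annotation
#'
#' Container for gene models and optional QTL intervals used by
#' [classify_location()], [coding_effect()] and [interval_overlap()].
#' All intervals are 0-based half-open bp.
#'
#' @param transcripts data.frame: `tx_id`, `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `coding` (logical; transcripts with CDS
#'   segments are coding regardless).
#' @param exons data.frame: `tx_id`, `start`, `end`.
#' @param cds optional data.frame: `tx_id`, `start`, `end`. Per transcript
#'   the CDS lengths should sum to a multiple of 3; offending transcripts
#'   are skipped (with a warning) by [coding_effect()].
#' @param qtl optional data.frame: `chrom`, `start`, `end` and optionally
#'   `id`, `trait`.
#' @param chrom_lengths optional named vector.
#' @return a `genome_annotation` list.
#' @export
genome_annotation <- function(transcripts, exons, cds = NULL, qtl = NULL,
                              chrom_lengths = NULL) {
  transcripts <- data.table::as.data.table(transcripts)
  exons <- data.table::as.data.table(exons)
  cds <- if (!is.null(cds)) data.table::as.data.table(cds)
  need <- c("tx_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(transcripts)))
    stopf("transcripts table needs columns %s", paste(need, collapse = ", "))
  if (!all(c("tx_id", "start", "end") %in% names(exons)))
    stopf("exons table needs tx_id, start, end")
  if (!"coding" %in% names(transcripts)) transcripts$coding <- FALSE
  if (!is.null(cds))
    transcripts$coding <- transcripts$coding | transcripts$tx_id %in% cds$tx_id
  if (any(transcripts$end <= transcripts$start)) stopf("empty transcript span")
  if (!is.null(qtl)) {
    qtl <- data.table::as.data.table(qtl)
    if (!all(c("chrom", "start", "end") %in% names(qtl)))
      stopf("qtl table needs chrom, start, end")
    if (!"id" %in% names(qtl)) qtl$id <- paste0("QTL", seq_len(nrow(qtl)))
  }
  structure(list(transcripts = transcripts, exons = exons, cds = cds,
                 qtl = qtl, chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 via `rtracklayer` and extracts transcript, exon and CDS
#' features into a [genome_annotation()] (coordinates converted to 0-based
#' half-open). Transcript-level features are recognized by type
#' (`mRNA`, `transcript`, `ncRNA`, `lnc_RNA`, `miRNA`, `tRNA`, `rRNA`,
#' `snRNA`, `snoRNA`); exons and CDS are attached through their `Parent`.
#'
#' @param gff3_path path to a GFF3 file.
#' @param qtl optional QTL table or BED path (see [read_qtl_bed()]).
#' @param chrom_lengths optional named vector.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(gff3_path, qtl = NULL, chrom_lengths = NULL) {
  g <- rtracklayer::import(gff3_path)
  md <- S4Vectors::mcols(g)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(g))
  parents <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  else rep(NA_character_, length(g))

  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "miRNA",
                "tRNA", "rRNA", "snRNA", "snoRNA")
  is_tx <- type %in% tx_types
  if (!any(is_tx)) stopf("no transcript-level features found in %s", gff3_path)
  transcripts <- data.table::data.table(
    tx_id = ids[is_tx],
    gene_id = parents[is_tx],
    chrom = as.character(GenomicRanges::seqnames(g))[is_tx],
    strand = as.character(BiocGenerics::strand(g))[is_tx],
    start = GenomicRanges::start(g)[is_tx] - 1L,
    end = GenomicRanges::end(g)[is_tx],
    coding = type[is_tx] == "mRNA")
  sub_tab <- function(t) {
    sel <- type == t & parents %in% transcripts$tx_id
    if (!any(sel)) return(NULL)
    data.table::data.table(tx_id = parents[sel],
                           start = GenomicRanges::start(g)[sel] - 1L,
                           end = GenomicRanges::end(g)[sel])
  }
  exons <- sub_tab("exon")
  if (is.null(exons))  # minimal models: treat the transcript span as one exon
    exons <- transcripts[, c("tx_id", "start", "end")]
  if (is.character(qtl) && length(qtl) == 1L) qtl <- read_qtl_bed(qtl)
  genome_annotation(transcripts, exons, cds = sub_tab("CDS"), qtl = qtl,
                    chrom_lengths = chrom_lengths)
}

#' Read QTL (or any feature) intervals from BED
#'
#' @param path BED path (0-based half-open; columns chrom, start, end and
#'   optionally name).
#' @return data.table `chrom`, `start`, `end`, `id`.
#' @export
read_qtl_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 3L) stopf("BED file needs at least 3 columns")
  out <- bed[, 1:3]
  data.table::setnames(out, c("chrom", "start", "end"))
  out$id <- if (ncol(bed) >= 4L) as.character(bed[[4L]])
            else paste0("QTL", seq_len(nrow(out)))
  out
}

# Introns per transcript: transcript span minus (reduced) exons.
intron_table <- function(ann) {
  tx <- ann$transcripts
  ex <- merge(ann$exons, tx[, c("tx_id", "chrom")], by = "tx_id")
  out <- lapply(seq_len(nrow(tx)), function(i) {
    e <- ex[ex$tx_id == tx$tx_id[i], ]
    if (!nrow(e)) return(NULL)
    span <- IRanges::IRanges(tx$start[i] + 1L, tx$end[i])
    introns <- IRanges::setdiff(span,
                                IRanges::IRanges(e$start + 1L, e$end))
    if (!length(introns)) return(NULL)
    data.table::data.table(tx_id = tx$tx_id[i], chrom = tx$chrom[i],
                           start = IRanges::start(introns) - 1L,
                           end = IRanges::end(introns))
  })
  data.table::rbindlist(out)
}

# 5'/3' UTR intervals derived from exon parts outside the CDS span,
# oriented by strand.
utr_table <- function(ann) {
  if (is.null(ann$cds)) return(list(utr5 = NULL, utr3 = NULL))
  tx <- ann$transcripts[ann$transcripts$coding == TRUE, ]
  u5 <- list(); u3 <- list()
  for (i in seq_len(nrow(tx))) {
    cd <- ann$cds[ann$cds$tx_id == tx$tx_id[i], ]
    ex <- ann$exons[ann$exons$tx_id == tx$tx_id[i], ]
    if (!nrow(cd) || !nrow(ex)) next
    cds_lo <- min(cd$start); cds_hi <- max(cd$end)
    parts <- IRanges::setdiff(IRanges::IRanges(ex$start + 1L, ex$end),
                              IRanges::IRanges(cds_lo + 1L, cds_hi))
    if (!length(parts)) next
    left <- parts[IRanges::end(parts) <= cds_lo]
    right <- parts[IRanges::start(parts) > cds_hi]
    as_dt <- function(ir) if (length(ir))
      data.table::data.table(chrom = tx$chrom[i],
                             start = IRanges::start(ir) - 1L,
                             end = IRanges::end(ir))
    if (tx$strand[i] == "+") {
      u5 <- c(u5, list(as_dt(left))); u3 <- c(u3, list(as_dt(right)))
    } else {
      u5 <- c(u5, list(as_dt(right))); u3 <- c(u3, list(as_dt(left)))
    }
  }
  list(utr5 = data.table::rbindlist(u5), utr3 = data.table::rbindlist(u3))
}

#' Classify SNP genomic locations into seven categories
#'
#' Assigns each SNP exactly one of: `coding`, `splicing`, `ncRNA`, `UTR5`,
#' `UTR3`, `intronic`, `updownstream`, `intergenic` (the coding category is
#' subtyped separately by [coding_effect()]). Precedence runs
#' coding = splicing > ncRNA > UTR5 > UTR3 > intronic > updownstream >
#' intergenic, so a SNP inside an intron of one gene and within 1 kb of
#' another is `intronic`. `updownstream` means within `flank` bp (default
#' 1 kb) of a transcript start/end; `splicing` means within `splice_bp`
#' (default 2) bp of an intron boundary, on the intron side.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based bp).
#' @param ann a [genome_annotation()].
#' @param flank up/downstream distance in bp.
#' @param splice_bp splice-junction distance in bp.
#' @return character vector of categories, one per SNP row.
#' @export
classify_location <- function(snps, ann, flank = 1000L, splice_bp = 2L) {
  stopifnot(inherits(ann, "genome_annotation"))
  snps <- data.table::as.data.table(snps)
  gr_snp <- granges_pos(snps$chrom, snps$pos)

  ann_chroms <- unique(ann$transcripts$chrom)
  off <- setdiff(unique(snps$chrom), ann_chroms)
  if (length(off))
    warnf("SNP(s) on unannotated chromosome(s) %s classified intergenic",
          paste(off, collapse = ", "))

  tx <- ann$transcripts
  ex <- merge(ann$exons, tx[, c("tx_id", "chrom")], by = "tx_id")
  introns <- intron_table(ann)
  utrs <- utr_table(ann)

  grl <- list()
  if (!is.null(ann$cds)) {
    cd <- merge(ann$cds, tx[, c("tx_id", "chrom")], by = "tx_id")
    grl$coding <- granges0(cd$chrom, cd$start, cd$end)
  }
  if (nrow(introns)) {
    don <- introns[, .(chrom, start, end = pmin(start + splice_bp, end))]
    acc <- introns[, .(chrom, start = pmax(end - splice_bp, start), end)]
    sp <- rbind(don, acc)
    grl$splicing <- granges0(sp$chrom, sp$start, sp$end)
  }
  nc <- tx[tx$coding == FALSE, ]
  if (nrow(nc)) grl$ncRNA <- granges0(nc$chrom, nc$start, nc$end)
  if (!is.null(utrs$utr5) && nrow(utrs$utr5))
    grl$UTR5 <- granges0(utrs$utr5$chrom, utrs$utr5$start, utrs$utr5$end)
  if (!is.null(utrs$utr3) && nrow(utrs$utr3))
    grl$UTR3 <- granges0(utrs$utr3$chrom, utrs$utr3$start, utrs$utr3$end)
  if (nrow(introns))
    grl$intronic <- granges0(introns$chrom, introns$start, introns$end)
  ud <- rbind(
    data.table::data.table(chrom = tx$chrom,
                           start = pmax(tx$start - as.integer(flank), 0L),
                           end = tx$start),
    data.table::data.table(chrom = tx$chrom, start = tx$end,
                           end = tx$end + as.integer(flank)))
  ud <- ud[ud$end > ud$start, ]
  if (nrow(ud)) grl$updownstream <- granges0(ud$chrom, ud$start, ud$end)

  out <- rep("intergenic", nrow(snps))
  undecided <- rep(TRUE, nrow(snps))
  for (cat in c("coding", "splicing", "ncRNA", "UTR5", "UTR3",
                "intronic", "updownstream")) {
    if (is.null(grl[[cat]])) next
    # seqlevel mismatches are expected for SNPs on unannotated
    # chromosomes (warned about above) and are not informative here
    hit <- suppressWarnings(
      GenomicRanges::countOverlaps(gr_snp, grl[[cat]])) > 0
    out[undecided & hit] <- cat
    undecided <- undecided & !hit
  }
  out
}

.effect_rank <- c("stop-gain" = 1L, "stop-loss" = 2L,
                  "nonsynonymous" = 3L, "synonymous" = 4L)

#' Coding effect of a SNP
#'
#' Translates the reference and alternate codons of a SNP lying in a CDS
#' with the standard genetic code, strand-aware (minus-strand transcripts
#' use reverse-complemented codons), and classifies the change as
#' `synonymous`, `nonsynonymous`, `stop-gain` or `stop-loss`. When several
#' transcripts contain the SNP the most severe call is returned
#' (stop-gain > stop-loss > nonsynonymous > synonymous). Transcripts whose
#' CDS length is not a multiple of 3 are skipped with a warning.
#'
#' @param chrom,pos,ref,alt the SNP (1-based position, single bases).
#' @param ann a [genome_annotation()] with CDS segments.
#' @param reference a named `Biostrings::DNAStringSet` (one entry per
#'   chromosome) or a FASTA path.
#' @return one of the four effect labels, or `NA` (with a warning) when the
#'   SNP is in no valid CDS.
#' @export
coding_effect <- function(chrom, pos, ref, alt, ann, reference) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (is.null(ann$cds)) stopf("annotation has no CDS segments")
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (!chrom %in% names(reference))
    stopf("chromosome %s absent from the reference", chrom)
  chromseq <- reference[[chrom]]

  cd_all <- merge(ann$cds, ann$transcripts[, c("tx_id", "chrom", "strand")],
                  by = "tx_id")
  cd_all <- cd_all[cd_all$chrom == chrom, ]
  pos0 <- pos - 1L
  tx_hit <- unique(cd_all$tx_id[cd_all$start <= pos0 & pos0 < cd_all$end])
  effects <- character(0)
  for (txid in tx_hit) {
    seg <- cd_all[cd_all$tx_id == txid, ]
    seg <- seg[order(seg$start), ]
    L <- sum(seg$end - seg$start)
    if (L %% 3L != 0L) {
      warnf("CDS of %s has length %d (not a multiple of 3); skipped", txid, L)
      next
    }
    # coding-strand CDS sequence and 0-based coding position of the SNP
    genomic_seq <- do.call(Biostrings::xscat, lapply(seq_len(nrow(seg)),
      function(i) Biostrings::subseq(chromseq, seg$start[i] + 1L, seg$end[i])))
    prior <- cumsum(c(0L, head(seg$end - seg$start, -1L)))
    k <- which(seg$start <= pos0 & pos0 < seg$end)
    goff <- prior[k] + (pos0 - seg$start[k])
    strand <- seg$strand[1]
    if (strand == "+") {
      cds_seq <- genomic_seq
      cpos <- goff
      alt_base <- alt
    } else {
      cds_seq <- Biostrings::reverseComplement(genomic_seq)
      cpos <- L - 1L - goff
      alt_base <- chartr("ACGT", "TGCA", alt)
    }
    codon_i <- cpos %/% 3L
    within <- cpos %% 3L
    ref_codon <- as.character(Biostrings::subseq(cds_seq, codon_i * 3L + 1L,
                                                 codon_i * 3L + 3L))
    ref_in_codon <- substr(ref_codon, within + 1L, within + 1L)
    expect_ref <- if (strand == "+") ref else chartr("ACGT", "TGCA", ref)
    if (ref_in_codon != expect_ref)
      warnf("reference base mismatch at %s:%d in %s", chrom, pos, txid)
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_base
    aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
    aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
    effects <- c(effects, if (aa_ref == aa_alt) "synonymous"
                 else if (aa_alt == "*") "stop-gain"
                 else if (aa_ref == "*") "stop-loss"
                 else "nonsynonymous")
  }
  if (!length(effects)) {
    warnf("SNP %s:%d lies in no valid CDS", chrom, pos)
    return(NA_character_)
  }
  names(sort(.effect_rank[unique(effects)]))[1]
}

#' Overlap between two interval sets
#'
#' Overlap means >= 1 shared bp on 0-based half-open intervals (abutting
#' intervals do not overlap). Reports both directional fractions -- e.g.
#' the fraction of DSSs hitting at least one QTL and the fraction of QTLs
#' hit by at least one DSS -- plus the per-query feature hits.
#'
#' @param query,features data.frames with `chrom`, `start`, `end`
#'   (0-based half-open); `features` may carry an `id` column.
#' @return list: `frac_query` (queries overlapping >= 1 feature),
#'   `frac_features` (features overlapping >= 1 query), `hits` data.table
#'   (`query_idx`, `feature_idx`, `feature_id`).
#' @export
interval_overlap <- function(query, features) {
  query <- data.table::as.data.table(query)
  features <- data.table::as.data.table(features)
  if (!nrow(query) || !nrow(features)) {
    return(list(frac_query = 0, frac_features = 0,
                hits = data.table::data.table(query_idx = integer(),
                                              feature_idx = integer(),
                                              feature_id = character())))
  }
  gq <- granges0(query$chrom, query$start, query$end)
  gf <- granges0(features$chrom, features$start, features$end)
  h <- GenomicRanges::findOverlaps(gq, gf)
  qi <- S4Vectors::queryHits(h)
  fi <- S4Vectors::subjectHits(h)
  ids <- if ("id" %in% names(features)) as.character(features$id)
         else as.character(seq_len(nrow(features)))
  list(frac_query = length(unique(qi)) / nrow(query),
       frac_features = length(unique(fi)) / nrow(features),
       hits = data.table::data.table(query_idx = qi, feature_idx = fi,
                                     feature_id = ids[fi]))
}

#' Group-specific SNPs and their nearly fixed subset
#'
#' A site is specific to the focal group when its alt allele is present
#' (`p > 0` among called alleles) in the focal group and absent (`p = 0`)
#' in every other group; frequencies are taken over called genotypes only,
#' and a group with no calls at a site is treated as not carrying the
#' allele. The nearly fixed subset additionally requires the focal
#' frequency to exceed `threshold` (strict; default 0.9).
#'
#' @param sites a [read_sites()] table covering >= 2 groups.
#' @param focal_group one of the table's group labels.
#' @param threshold fixation threshold.
#' @return list of data.tables `specific` and `nearly_fixed`.
#' @export
group_specific_snps <- function(sites, focal_group, threshold = 0.9) {
  groups <- attr(sites, "groups")
  if (is.null(groups) || !focal_group %in% groups)
    stopf("focal group '%s' not present in site table", focal_group)
  others <- setdiff(groups, focal_group)
  pf <- sites[[paste0("p_", focal_group)]]
  present_focal <- !is.na(pf) & pf > 0
  absent_others <- Reduce(`&`, lapply(others, function(g) {
    p <- sites[[paste0("p_", g)]]
    is.na(p) | p == 0
  }))
  specific <- present_focal & absent_others
  fixed <- specific & pf > threshold
  out <- list(specific = sites[specific], nearly_fixed = sites[fixed])
  for (x in out) data.table::setattr(x, "groups", groups)
  out
}

#' Category enrichment versus genome composition
#'
#' Observed-over-expected ratio per category: values above 1 indicate
#' enrichment of the SNP set in that category relative to the genome's
#' compositional fraction, below 1 depletion.
#'
#' @param observed named numeric vector of observed category fractions.
#' @param genome named numeric vector of genome composition fractions
#'   (same names).
#' @return named numeric vector of ratios; NA (with a warning) where the
#'   genome fraction is zero.
#' @export
category_enrichment <- function(observed, genome) {
  cats <- names(observed)
  if (is.null(cats) || !all(cats %in% names(genome)))
    stopf("observed and genome fractions must share category names")
  g <- genome[cats]
  if (any(g == 0)) warnf("zero genome fraction: ratio undefined for %s",
                         paste(cats[g == 0], collapse = ", "))
  ratio <- ifelse(g > 0, observed / g, NA_real_)
  stats::setNames(as.numeric(ratio), cats)
}
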