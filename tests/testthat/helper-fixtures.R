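# Fixture builders used across test files. Everything is generated in code;
# no data files ship with the tests.

library(data.table)

# Minimal VCF writer for hand-crafted sites. `rows` is a data.frame with
# chrom, pos, ref, alt, info (string) and one column per sample holding GT
# strings.
write_test_vcf <- function(path, rows, samples,
                           contigs = c(chr1 = 1000000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"x\">",
            c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum",
              "InbreedingCoeff")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(rows)), function(i)
    paste(c(rows$chrom[i], rows$pos[i], ".", rows$ref[i], rows$alt[i],
            ".", ".", rows$info[i], "GT",
            unlist(rows[i, samples, drop = FALSE])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}

# Two-group site table built directly (bypasses VCF parsing) for the window
# and permutation-null tests.
make_site_table <- function(chrom, pos,
                            n_A, p_A, h_A, pi_A,
                            n_B, p_B, h_B, pi_B) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos),
                   n_A = n_A, p_A = p_A, h_A = h_A, pi_A = pi_A,
                   n_B = n_B, p_B = p_B, h_B = h_B, pi_B = pi_B)
  setattr(dt, "groups", c("A", "B"))
  dt
}

# Per-group site summaries from a dosage matrix, mirroring the read_sites
# definitions (independent recomputation used for round-trip checks and for
# building scan tables without file IO).
site_table_from_genotypes <- function(geno, sample_groups, chrom, pos) {
  groups <- unique(sample_groups)
  dt <- data.table(chrom = chrom, pos = as.integer(pos))
  for (g in groups) {
    d <- geno[, sample_groups == g, drop = FALSE]
    n <- rowSums(!is.na(d))
    ac <- rowSums(d, na.rm = TRUE)
    nall <- 2 * n
    dt[[paste0("n_", g)]] <- n
    dt[[paste0("p_", g)]] <- ifelse(n > 0, ac / nall, NA_real_)
    dt[[paste0("h_", g)]] <- ifelse(n > 0,
                                    rowSums(d == 1, na.rm = TRUE) / n,
                                    NA_real_)
    dt[[paste0("pi_", g)]] <- ifelse(nall >= 2,
                                     2 * ac * (nall - ac) /
                                       (nall * (nall - 1)),
                                     NA_real_)
  }
  setattr(dt, "groups", groups)
  dt
}

# A small coding + noncoding gene model on one chromosome, used by the
# annotation tests. Layout (0-based half-open, chromosome "chrA"):
#   geneP (+): tx span [2000, 5000); exons [2000,2600) and [4000,5000);
#              CDS [2200,2600) + [4000,4400); UTR5 [2000,2200),
#              UTR3 [4400,5000); intron [2600,4000)
#   geneM (-): tx span [8000, 9200); single exon = CDS [8000,9200)? no --
#              exon [8000,9200), CDS [8300,9000)
#   ncR   (.): noncoding span [12000, 12500)
toy_annotation <- function(qtl = NULL) {
  transcripts <- data.table(
    tx_id = c("txP", "txM", "txN"),
    gene_id = c("geneP", "geneM", "ncR"),
    chrom = "chrA",
    strand = c("+", "-", "+"),
    start = c(2000L, 8000L, 12000L),
    end = c(5000L, 9200L, 12500L),
    coding = c(TRUE, TRUE, FALSE))
  exons <- data.table(
    tx_id = c("txP", "txP", "txM", "txN"),
    start = c(2000L, 4000L, 8000L, 12000L),
    end = c(2600L, 5000L, 9200L, 12500L))
  cds <- data.table(
    tx_id = c("txP", "txP", "txM"),
    start = c(2200L, 4000L, 8300L),
    end = c(2600L, 4400L, 9000L))
  genome_annotation(transcripts, exons, cds, qtl = qtl,
                    chrom_lengths = c(chrA = 20000L))
}

# Reference sequence for chrA with controlled codons inside the txP CDS.
# The CDS of txP is 400 + 400 = 800 bp (multiple of 3 fails: 800 %% 3 != 0).
# To keep translation valid the tests use a dedicated annotation+sequence
# pair built by toy_coding_fixture().
toy_coding_fixture <- function() {
  # one + strand gene: CDS [100, 112) = 12 bp, codons at 100..102, 103..105,
  # 106..108, 109..111; one - strand gene: CDS [200, 212).
  transcripts <- data.table(
    tx_id = c("txF", "txR"), gene_id = c("gF", "gR"), chrom = "chrB",
    strand = c("+", "-"), start = c(100L, 200L), end = c(112L, 212L),
    coding = TRUE)
  exons <- data.table(tx_id = c("txF", "txR"), start = c(100L, 200L),
                      end = c(112L, 212L))
  cds <- data.table(tx_id = c("txF", "txR"), start = c(100L, 200L),
                    end = c(112L, 212L))
  ann <- genome_annotation(transcripts, exons, cds)
  seq <- paste(rep("A", 300), collapse = "")
  # + strand codons: CGG GGA TGG TAG  (pos 101..112, 1-based)
  substr(seq, 101, 112) <- "CGGGGATGGTAG"
  # - strand gene: coding sequence read on the minus strand. Genomic
  # [201,212] (1-based) = reverse complement of the coding sequence
  # "ATGCGGTGGTAA" -> genomic "TTACCACCGCAT".
  substr(seq, 201, 212) <- "TTACCACCGCAT"
  ref <- Biostrings::DNAStringSet(c(chrB = seq))
  list(ann = ann, ref = ref)
}

# Shared simulation settings used by the calibration-style tests: two groups
# of 25 diploids diverged at F = 0.05 on a 10 Mb chromosome with ~50,000
# polymorphic sites.
neutral_config <- function(seed, sweeps = NULL, n_bp = 1e7,
                           density = 0.005) {
  sim_config(chrom_lengths = c(chr1 = n_bp), snp_density = density,
             n_groups = 2L, n_per_group = 25L, f_bg = 0.05,
             sweeps = sweeps, seed = seed)
}

# Five 200-kb sweeps pushed in group 1, evenly spaced on the 10 Mb
# chromosome.
planted_sweeps <- function() {
  starts <- c(1e6, 2.8e6, 4.6e6, 6.4e6, 8.2e6)
  rbindlist(lapply(starts, function(s)
    sweep_spec("chr1", s, s + 2e5, target_group = 1L,
               f_sweep = 0.6, s = 0.9)))
}
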