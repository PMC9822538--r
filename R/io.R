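#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag BamFile indexFa
#' @importFrom Biostrings DNAStringSet writeXStringSet
NULL

phred_chars <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), "")
}

# CIGAR, SEQ and QUAL strings for one read (per-read form from get_read()).
build_sam_fields <- function(rd) {
  sym <- rd$sym; n <- length(sym)
  rel_ins <- if (nrow(rd$ins)) rd$ins$pos - rd$start + 1L else integer(0)
  ord <- order(rel_ins)
  rel_ins <- rel_ins[ord]
  ins_len <- rd$ins$len[ord]; ins_seq <- rd$ins$seq[ord]; ins_qual <- rd$ins$qual[ord]

  isD <- sym == 5L
  r <- rle(isD)
  seg_end <- cumsum(r$lengths); seg_start <- seg_end - r$lengths + 1L
  ops <- character(0); lens <- integer(0)
  seqp <- character(0); qualp <- character(0)
  for (sgi in seq_along(r$lengths)) {
    a <- seg_start[sgi]; b <- seg_end[sgi]
    if (r$values[sgi]) { ops <- c(ops, "D"); lens <- c(lens, b - a + 1L); next }
    anchors <- rel_ins[rel_ins >= a & rel_ins <= b]
    cuts <- c(a - 1L, anchors, b)          # M pieces end at each anchor
    for (ci in seq_len(length(cuts) - 1L)) {
      lo <- cuts[ci] + 1L; hi <- cuts[ci + 1L]
      if (hi >= lo) {
        ops <- c(ops, "M"); lens <- c(lens, hi - lo + 1L)
        seqp <- c(seqp, paste0(SYMBOLS[sym[lo:hi]], collapse = ""))
        qualp <- c(qualp, paste0(intToUtf8(rd$qual[lo:hi] + 33L,
                                           multiple = TRUE), collapse = ""))
      }
      if (ci < length(cuts) - 1L) {        # the insertion after this piece
        k <- which(rel_ins == cuts[ci + 1L])[1]
        ops <- c(ops, "I"); lens <- c(lens, ins_len[k])
        seqp <- c(seqp, ins_seq[k]); qualp <- c(qualp, ins_qual[k])
      }
    }
  }
  # merge adjacent identical ops (an anchor at a piece boundary can split M)
  keep <- c(TRUE, ops[-1] != ops[-length(ops)] | ops[-length(ops)] == "I")
  grp <- cumsum(keep)
  lens <- tapply(lens, grp, sum)
  ops <- ops[keep]
  list(cigar = paste0(lens, ops, collapse = ""),
       seq = paste0(seqp, collapse = ""),
       qual = paste0(qualp, collapse = ""))
}

#' Write simulator truth files: FASTA, sorted+indexed BAM, VCF, BED
#'
#' Emits `<prefix>.fasta` (+ `.fai`), `<prefix>.bam` (+ `.bai`,
#' coordinate-sorted, with the truth haplotype in the `XH` integer tag and
#' any working haplotag in `HP`), `<prefix>.truth.vcf` (1-based truth
#' variants) and `<prefix>.bed` (whole-contig confident region).
#'
#' @param genome a [generate_diploid()] result.
#' @param readset a [simulate_reads()] result.
#' @param out_prefix output path prefix.
#' @param fastq also write `<prefix>.fastq` (reads as sequenced, for
#'   optional re-alignment with an external aligner).
#' @return named list of file paths.
#' @export
write_truth <- function(genome, readset, out_prefix, fastq = FALSE) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  fa <- paste0(out_prefix, ".fasta")
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$reference, genome$contig))
  Biostrings::writeXStringSet(dna, fa)
  Rsamtools::indexFa(fa)

  sam <- paste0(out_prefix, ".sam")
  bam <- write_read_set_bam(readset, sam, paste0(out_prefix, ".bam"))
  unlink(sam)

  vcf <- paste0(out_prefix, ".truth.vcf")
  write_truth_vcf(genome, vcf)

  bed <- paste0(out_prefix, ".bed")
  writeLines(sprintf("%s\t0\t%d", genome$contig, nchar(genome$reference)), bed)

  out <- list(fasta = fa, bam = bam, vcf = vcf, bed = bed)
  if (fastq) {
    fq <- paste0(out_prefix, ".fastq")
    con <- file(fq, "w")
    for (i in seq_len(n_reads(readset))) {
      rd <- get_read(readset, i)
      f <- build_sam_fields(rd)
      writeLines(c(paste0("@", rd$name), f$seq, "+", f$qual), con)
    }
    close(con)
    out$fastq <- fq
  }
  out
}

#' Write a haplotagged BAM
#'
#' Exports a read set with its working haplotype assignments as a
#' coordinate-sorted, indexed BAM carrying the per-read `HP` tag
#' (unphased reads carry no tag).
#'
#' @param rs a `read_set` (tag with [set_haplotags()] first).
#' @param bam_path output BAM path.
#' @return the BAM path, invisibly.
#' @export
write_haplotagged_bam <- function(rs, bam_path) {
  sam <- tempfile(fileext = ".sam")
  out <- write_read_set_bam(rs, sam, bam_path)
  unlink(sam)
  invisible(out)
}

#' Write phased heterozygous sites as a VCF with phase-set annotations
#'
#' Phased genotypes use the `|` separator (`0|1` when the first allele
#' is on haplotype 1) and the `PS` FORMAT field carries the phase-block
#' identifier.
#'
#' @param phased a [phase_sites()] result with `ref` alleles attached
#'   via `ref`.
#' @param ref reference base vector for the contig.
#' @param contig,contig_length contig metadata.
#' @param path output path.
#' @export
write_phased_vcf <- function(phased, ref, contig, contig_length, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=haplosnp-phaser",
               sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"),
             con)
  if (nrow(phased)) {
    rb <- ref[phased$pos0 + 1L]
    # alleles relative to the reference base; hap1 allele first
    alt <- ifelse(phased$hap1 == rb, phased$hap2, phased$hap1)
    gt <- ifelse(phased$hap1 == rb, "0|1", "1|0")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:PS\t%s:%d",
                       contig, phased$pos0 + 1L, rb, alt, gt, phased$block),
               con)
  }
  close(con)
  invisible(path)
}

# SAM text for a read_set, converted to a sorted+indexed BAM.
write_read_set_bam <- function(rs, sam_path, bam_path) {
  con <- file(sam_path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", rs$contig, rs$contig_length)), con)
  ord <- order(rs$reads$start)
  for (i in ord) {
    rd <- get_read(rs, i)
    f <- build_sam_fields(rd)
    flag <- if (rd$strand == "-") 16L else 0L
    tags <- sprintf("XH:i:%d", rd$truth_hap)
    if (rd$hap > 0L) tags <- paste0(tags, sprintf("\tHP:i:%d", rd$hap))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
                       rd$name, flag, rs$contig, rd$start + 1L, rd$mapq,
                       f$cigar, f$seq, f$qual, tags), con)
  }
  close(con)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = TRUE)
}

write_truth_vcf <- function(genome, path) {
  v <- genome$truth_variants
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genome$contig,
                       nchar(genome$reference)),
               "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      "TRUTH")), con)
  if (nrow(v)) {
    gt <- ifelse(v$zyg == "het", "0/1", "1/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVC=%s\tGT\t%s",
                       genome$contig, v$pos0 + 1L, v$ref, v$alt, v$class, gt),
               con)
  }
  close(con)
  path
}

#' Read a coordinate-sorted BAM into a `read_set`
#'
#' Expands each alignment's CIGAR into per-reference-position aligned
#' symbols (insertions are attached to the aligned base immediately to
#' their left). Secondary/supplementary/unmapped alignments and reads
#' below `min_mapq` are excluded (standard pileup hygiene).
#'
#' @param bam path to an indexed BAM.
#' @param contig contig to load (default: first in the header).
#' @param contig_length contig length; taken from the header if `NULL`.
#' @param min_mapq minimum mapping quality (default 1, i.e. MAPQ 0 excluded).
#' @return a [new_read_set()] object. Truth haplotype is taken from the
#'   `XH` tag and working haplotags from `HP` when present.
#' @export
read_alignments <- function(bam, contig = NULL, contig_length = NULL,
                            min_mapq = 1L) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(contig)) contig <- names(hdr)[1]
  if (!contig %in% names(hdr)) stop("contig not found in BAM header: ", contig)
  if (is.null(contig_length)) contig_length <- unname(hdr[contig])

  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("XH", "HP"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  sel <- which(as.character(x$rname) == contig & x$mapq >= min_mapq)

  n <- length(sel)
  reads_meta <- vector("list", n)
  b_read <- b_pos <- b_sym <- b_qual <- vector("list", n)
  ins_list <- vector("list", n)
  seqs <- as.character(x$seq[sel])
  quals <- as.character(x$qual[sel])
  xh <- x$tag$XH; hp <- x$tag$HP

  for (k in seq_len(n)) {
    i <- sel[k]
    cig <- x$cigar[i]
    oplen <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    opchr <- regmatches(cig, gregexpr("[MIDNSHP=X]", cig))[[1]]
    qv <- utf8ToInt(quals[k]) - 33L
    sv <- strsplit(seqs[k], "")[[1]]
    rpos <- x$pos[i] - 1L                  # 0-based reference cursor
    qpos <- 1L
    nop <- length(opchr)
    pos_l <- sym_l <- qq_l <- vector("list", nop)
    ipos_l <- ilen_l <- iseq_l <- iqual_l <- vector("list", nop)
    for (j in seq_len(nop)) {
      op <- opchr[j]; l <- oplen[j]
      if (op %in% c("M", "=", "X")) {
        pos_l[[j]] <- rpos:(rpos + l - 1L)
        sym_l[[j]] <- match(sv[qpos:(qpos + l - 1L)], SYMBOLS)
        qq_l[[j]] <- qv[qpos:(qpos + l - 1L)]
        rpos <- rpos + l; qpos <- qpos + l
      } else if (op == "D" || op == "N") {
        pos_l[[j]] <- rpos:(rpos + l - 1L)
        sym_l[[j]] <- rep(5L, l); qq_l[[j]] <- rep(0L, l)
        rpos <- rpos + l
      } else if (op == "I") {
        ipos_l[[j]] <- rpos - 1L; ilen_l[[j]] <- l
        iseq_l[[j]] <- paste0(sv[qpos:(qpos + l - 1L)], collapse = "")
        iqual_l[[j]] <- paste0(intToUtf8(qv[qpos:(qpos + l - 1L)] + 33L,
                                         multiple = TRUE), collapse = "")
        qpos <- qpos + l
      } else if (op == "S") {
        qpos <- qpos + l
      }                                    # H, P consume nothing here
    }
    pos <- unlist(pos_l); sym <- unlist(sym_l); qq <- unlist(qq_l)
    ipos <- unlist(ipos_l); ilen <- unlist(ilen_l)
    iseq <- unlist(iseq_l); iqual <- unlist(iqual_l)
    if (is.null(ipos)) { ipos <- integer(0); ilen <- integer(0)
                         iseq <- character(0); iqual <- character(0) }
    reads_meta[[k]] <- data.frame(
      name = x$qname[i], strand = if (bitwAnd(x$flag[i], 16L)) "-" else "+",
      mapq = x$mapq[i], start = pos[1], end = pos[length(pos)] + 1L,
      hap = if (!is.null(hp) && !is.na(hp[i])) as.integer(hp[i]) else 0L,
      truth_hap = if (!is.null(xh) && !is.na(xh[i])) as.integer(xh[i]) else 0L)
    b_read[[k]] <- rep(k, length(pos)); b_pos[[k]] <- pos
    b_sym[[k]] <- sym; b_qual[[k]] <- qq
    ins_list[[k]] <- if (length(ipos))
      data.frame(read = k, pos = ipos, len = ilen, seq = iseq, qual = iqual)
    else NULL
  }
  reads <- do.call(rbind, reads_meta)
  if (is.null(reads))
    reads <- data.frame(name = character(), strand = character(),
                        mapq = integer(), start = integer(), end = integer(),
                        hap = integer(), truth_hap = integer())
  rownames(reads) <- NULL
  ins <- do.call(rbind, c(ins_list,
                          list(data.frame(read = integer(), pos = integer(),
                                          len = integer(), seq = character(),
                                          qual = character()))))
  new_read_set(contig, contig_length, reads,
               list(read = unlist(b_read), pos = unlist(b_pos),
                    sym = unlist(b_sym), qual = unlist(b_qual)), ins)
}

#' Reconstruct a truth-variant table from a truth VCF
#'
#' Inverse of the simulator's truth VCF writer: returns a
#' `truth_variants`-shaped data.frame (`pos0`, `ref`, `alt`, `zyg`,
#' `class`, `len`) usable for training-label generation.
#'
#' @param path truth VCF path.
#' @return data.frame in [generate_diploid()] truth format.
#' @export
truth_from_vcf <- function(path) {
  v <- read_simple_vcf(path)
  nr <- nchar(v$ref); na <- nchar(v$alt)
  data.frame(pos0 = v$pos0, ref = v$ref, alt = v$alt,
             zyg = ifelse(v$gt %in% c("0/1", "0|1", "1|0"), "het", "hom_alt"),
             class = ifelse(nr == 1L & na == 1L, "SNP",
                            ifelse(na > nr, "INS", "DEL")),
             hap = 0L, len = abs(na - nr))
}

#' Read a (simple, single-sample) VCF into a data.frame
#'
#' Lightweight parser for the VCFs this package writes: returns 0-based
#' `pos0`, `ref`, `alt` (comma-split into `alt1`/`alt2`), `qual`, and the
#' genotype string `gt`.
#'
#' @param path VCF path.
#' @return data.frame with one row per record.
#' @export
read_simple_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln))
    return(data.frame(contig = character(), pos0 = integer(),
                      ref = character(), alt = character(), qual = numeric(),
                      gt = character()))
  f <- strsplit(ln, "\t")
  get <- function(k) vapply(f, `[[`, "", k)
  gt <- vapply(f, function(x) if (length(x) >= 10)
    strsplit(x[10], ":")[[1]][1] else NA_character_, "")
  data.frame(contig = get(1), pos0 = as.integer(get(2)) - 1L,
             ref = get(4), alt = get(5),
             qual = suppressWarnings(as.numeric(get(6))), gt = gt)
}
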