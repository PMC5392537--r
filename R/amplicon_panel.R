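# Bisulfite PCR amplicon panel.
#
# An amplicon couples a target CpG (Illumina-style id, GRCh37 coordinate)
# with a primer pair designed in bisulfite space, the bisulfite-converted
# reference sequence of the product, the 0-based offsets of interrogated
# CpG cytosines (target + co-analysed adjacent CpGs), and the offsets of
# non-CpG cytosines that act as bisulfite conversion controls (they must
# read T after complete conversion; their residual C fraction measures
# conversion failure). Primers never cover a CpG, so methylation state
# cannot bias amplification.
#
# Sequence conventions:
#  * genomic coordinates 1-based (as printed for array CpGs);
#  * within-amplicon offsets 0-based half-open;
#  * bisulfite-converted reference: non-CpG C -> T, CpG C kept as the
#    IUPAC ambiguity Y (matches C and T), so one reference serves both
#    methylated and unmethylated molecules.

#' Bisulfite-convert a DNA sequence in silico
#'
#' Non-CpG cytosines become T; CpG cytosines become `cpg_as` (default the
#' IUPAC code `Y`, matching both the methylated C and the converted T).
#' An existing `Y` in the input is left untouched, so converted
#' references round-trip.
#'
#' @param seq DNA string (character scalar).
#' @param cpg_as replacement for CpG cytosines: `"Y"`, `"C"` (fully
#'   methylated template) or `"T"` (fully unmethylated).
#' @return converted sequence (character scalar).
#' @export
bisulfite_convert <- function(seq, cpg_as = "Y") {
  ch <- strsplit(toupper(seq), "")[[1L]]
  is_c <- ch == "C"
  next_g <- c(ch[-1L] == "G", FALSE)
  ch[is_c & next_g] <- cpg_as
  ch[is_c & !next_g] <- "T"
  paste(ch, collapse = "")
}

# match positions allowing IUPAC ambiguity in the subject
match_primer <- function(primer, subject) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer), Biostrings::DNAString(subject),
    fixed = FALSE)
  IRanges::start(hits)
}

#' In-silico bisulfite PCR
#'
#' Generates both bisulfite PCR template strands (top and bottom, each
#' converted with non-CpG C→T and CpG C left ambiguous as `Y`), searches
#' the forward primer and the reverse complement of the reverse primer
#' with Y-ambiguity, and returns the unique product. Because the CpG
#' ambiguity matches both C and T, a fully methylated and a fully
#' unmethylated template yield the same product.
#'
#' @param genomic_seq genomic DNA covering the target region (suggested:
#'   ±1 kb around the CpG of interest).
#' @param fwd_primer,rev_primer primers in bisulfite space (5'→3').
#' @return `NULL` if no product; otherwise a list with `length` (bp,
#'   inclusive of both primers), `template_strand` (`"top-converted"` or
#'   `"bottom-converted"`), `reference_seq` (converted product, CpG
#'   cytosines as `Y`), `genomic_product`, `cpg_offsets` and
#'   `control_offsets` (0-based, primer regions excluded), `start`
#'   (1-based product start on the given strand of `genomic_seq`).
#'   Multiple distinct products raise an error of class
#'   `methage_multi_hit`.
#' @export
in_silico_bisulfite_pcr <- function(genomic_seq, fwd_primer, rev_primer) {
  genomic_seq <- toupper(genomic_seq)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  strands <- list(`top-converted` = genomic_seq,
                  `bottom-converted` = revcomp(genomic_seq))
  rc_rev <- revcomp(rev_primer)
  products <- list()
  for (strand in names(strands)) {
    genomic <- strands[[strand]]
    template <- bisulfite_convert(genomic, cpg_as = "Y")
    fs <- match_primer(fwd_primer, template)
    rs <- match_primer(rc_rev, template)
    for (s in fs) {
      ends <- rs + nchar(rc_rev) - 1L
      ends <- ends[rs >= s + nchar(fwd_primer)]
      for (e in ends) {
        products[[length(products) + 1L]] <- list(
          length = e - s + 1L, template_strand = strand,
          reference_seq = substr(template, s, e),
          genomic_product = substr(genomic, s, e), start = s)
      }
    }
  }
  if (!length(products)) return(NULL)
  if (length(products) > 1L) {
    sigs <- vapply(products, function(p)
      paste(p$template_strand, p$start, p$length), "")
    if (length(unique(sigs)) > 1L)
      stop(structure(class = c("methage_multi_hit", "error", "condition"),
                     list(message = sprintf(
                       "ambiguous in-silico PCR: %d products", length(products)),
                       call = sys.call())))
  }
  p <- products[[1L]]
  offs <- derive_offsets(p$genomic_product, nchar(fwd_primer),
                         nchar(rev_primer))
  c(p, offs)
}

# CpG and conversion-control cytosine offsets of a genomic product,
# excluding the primer-covered ends (those bases come from the primers,
# not the template, so they carry no methylation/conversion signal)
derive_offsets <- function(genomic_product, fwd_len, rev_len) {
  ch <- strsplit(genomic_product, "")[[1L]]
  L <- length(ch)
  is_c <- ch == "C"
  next_g <- c(ch[-1L] == "G", FALSE)
  interior <- seq_along(ch) > fwd_len & seq_along(ch) <= L - rev_len
  list(cpg_offsets = which(is_c & next_g & interior) - 1L,
       control_offsets = which(is_c & !next_g & interior) - 1L)
}

#' Build one amplicon record
#'
#' Validates the panel design rules: primers must not contain a CpG
#' dinucleotide, offsets must be disjoint and inside the reference, and
#' the stated length must match the reference.
#'
#' @param cpg_id Illumina-style id of the target CpG.
#' @param gene gene symbol.
#' @param chrom chromosome name.
#' @param position 1-based GRCh37 coordinate of the target CpG cytosine.
#' @param fwd_primer,rev_primer bisulfite-space primers.
#' @param template_strand `"top-converted"` or `"bottom-converted"`.
#' @param reference_seq bisulfite-space amplicon (CpG cytosines as `Y`),
#'   including primers.
#' @param cpg_offsets 0-based offsets of interrogated CpG cytosines.
#' @param target_cpg_offset offset corresponding to `cpg_id`.
#' @param control_offsets 0-based offsets of conversion-control
#'   cytosines.
#' @param anneal_temp annealing temperature (°C).
#' @param annotation free text.
#' @return a list of class `amplicon`.
#' @export
amplicon <- function(cpg_id, gene, chrom, position, fwd_primer,
                     rev_primer,
                     template_strand = c("top-converted",
                                         "bottom-converted"),
                     reference_seq, cpg_offsets, target_cpg_offset,
                     control_offsets, anneal_temp = NA_real_,
                     annotation = "") {
  template_strand <- match.arg(template_strand)
  for (p in c(fwd = fwd_primer, rev = rev_primer)) {
    if (grepl("CG", toupper(p)))
      stop("primer for ", cpg_id, " contains a CpG dinucleotide: ", p)
  }
  L <- nchar(reference_seq)
  if (position < 1) stop("position must be >= 1 for ", cpg_id)
  offs <- c(cpg_offsets, control_offsets)
  if (any(offs < 0 | offs >= L))
    stop("offsets out of range [0, ", L, ") for ", cpg_id)
  if (length(intersect(cpg_offsets, control_offsets)))
    stop("cpg_offsets and control_offsets overlap for ", cpg_id)
  if (!target_cpg_offset %in% cpg_offsets)
    stop("target_cpg_offset must be one of cpg_offsets for ", cpg_id)
  structure(list(
    cpg_id = cpg_id, gene = gene, chrom = as.character(chrom),
    position = as.integer(position), fwd_primer = toupper(fwd_primer),
    rev_primer = toupper(rev_primer), template_strand = template_strand,
    reference_seq = toupper(reference_seq), length = L,
    cpg_offsets = as.integer(cpg_offsets),
    target_cpg_offset = as.integer(target_cpg_offset),
    control_offsets = as.integer(control_offsets),
    anneal_temp = anneal_temp, annotation = annotation),
    class = "amplicon")
}

#' Assemble a marker panel
#'
#' @param amplicons list of [amplicon()] records.
#' @return object of class `marker_panel` (a named list of amplicons).
#' @export
marker_panel <- function(amplicons) {
  if (!length(amplicons)) stop("empty panel")
  ids <- vapply(amplicons, `[[`, "", "cpg_id")
  if (anyDuplicated(ids))
    stop("duplicate cpg_id in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(amplicons, ids), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", length(x), "bisulfite PCR amplicons\n")
  for (a in x)
    cat(sprintf("  %s %s %s:%s  %d bp, %d CpG offsets, %d controls\n",
                a$cpg_id, a$gene, a$chrom,
                format(a$position, big.mark = ","), a$length,
                length(a$cpg_offsets), length(a$control_offsets)))
  invisible(x)
}

#' Save / load a marker panel (JSON)
#'
#' @param panel a `marker_panel`.
#' @param path JSON file.
#' @return `save_panel` returns `path` invisibly; `load_panel` a
#'   validated `marker_panel` (violations reported with the marker id).
#' @export
save_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  obj <- lapply(unname(panel), function(a) {
    a <- unclass(a)
    a[c("cpg_id", "gene", "chrom", "position", "fwd_primer", "rev_primer",
        "template_strand", "reference_seq", "cpg_offsets",
        "target_cpg_offset", "control_offsets", "anneal_temp",
        "annotation")]
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_panel
#' @export
load_panel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse panel file ",
                                           path, ": ", conditionMessage(e)))
  if (!length(obj)) stop("empty panel file: ", path)
  amps <- lapply(obj, function(a)
    amplicon(a$cpg_id, a$gene, a$chrom, a$position, a$fwd_primer,
             a$rev_primer, a$template_strand, a$reference_seq,
             unlist(a$cpg_offsets), a$target_cpg_offset,
             unlist(a$control_offsets),
             if (is.null(a$anneal_temp)) NA_real_ else a$anneal_temp,
             if (is.null(a$annotation)) "" else a$annotation))
  marker_panel(amps)
}

#' Export panel reference sequences as FASTA
#'
#' One record per marker (id = cpg_id), bisulfite-space with CpG
#' cytosines as `Y`.
#'
#' @param panel a `marker_panel`.
#' @param path FASTA file.
#' @export
panel_reference_fasta <- function(panel, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(panel, `[[`, "", "reference_seq"))
  names(seqs) <- vapply(panel, `[[`, "", "cpg_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# --- packaged 16-marker panel ------------------------------------------

# Primer pairs, product lengths and annealing temperatures of the 16
# designed singleplex bisulfite PCR assays, plus the GRCh37 coordinate
# and gene of each target CpG. These are assay design constants; the
# reference sequences built around them are synthetic (see
# build_synthetic_panel).
panel16_assays <- function() {
  read_tbl <- function(lines) utils::read.delim(text = lines,
                                                stringsAsFactors = FALSE)
  read_tbl(c(
    "cpg_id\tgene\tchrom\tposition\tfwd\trev\tlen\ttm",
    "cg19761273\tCSNK1D\t17\t80232096\tTGTTTAGTTTGAAGATTGAG\tCCTTATTTCCTTTACAAAAA\t150\t50",
    "cg27544190\tC21orf63\t21\t33785434\tGGGTAGGATTAAAGTTGA\tCTTAAAAATAACAATCCCC\t106\t50",
    "cg03286783\tCASC4\t15\t44580973\tGTTTTAGTTAGTGGGTG\tCCCCTCCTCAAATCAAA\t181\t52",
    "cg01511567\tSSRP1\t11\t57103631\tTATTAGATTTAGTATAGGGG\tCCCACAACTATTCAAATA\t132\t50",
    "cg07158339\tFXN\t9\t71650237\tGGAATATGTTTTGTTTAAAA\tTAATTAACCTCTCTATACCT\t122\t48",
    "cg05442902\tP2RXL1\t22\t21369010\tGTATGTTTTGGTTTTTGT\tAATAACCTCTAAACTAACC\t109\t52",
    "cg24450312\tRASSF5\t1\t206681158\tGTTATTTATAGAGTTTGAG\tTCTACTACAAACCAAA\t201\t50",
    "cg17274064\tERG\t21\t40033892\tAGGGAATAAGTATTTTTT\tCTCACAATCAAACTTCTATATAC\t139\t48",
    "cg02085507\tTRIP10\t19\t6739192\tGTTAATGGATTTGGTTTTG\tAACTCAAAAAATCCTTCCT\t186\t48",
    "cg20692569\tFZD9\t7\t72848481\tTTGTTGTTGTGGTAGT\tAACCCAACAAATTAAA\t160\t48",
    "cg04528819\tKLF14\t7\t130418315\tAATAGGTTTTGGTGTAGTT\tCAACCTCTAATAAATTCTCT\t138\t50",
    "cg08370996\tNR2F2\t15\t96874031\tGTGTTAAAGTTTATTATATAGA\tAAAAAAAAAAACACACAC\t187\t52",
    "cg04084157\tVGF\t7\t100809049\tGAGGGTGTTTGTTTTTTT\tAACATTTCATTCATTCATTC\t111\t52",
    "cg22736354\tNHLRC1\t6\t18122719\tGTTGAGTTTAGGAGTTTTAT\tCTTTAAAAAATTTAACCACC\t201\t52",
    "cg06493994\tSCGN\t6\t25652602\tGGAGAGTAAGTTAAGAAATA\tAACCTACCAAAAACCAAC\t150\t52",
    "cg02479575\tC19orf30\t19\t4769653\tGGAGGAGAATGTTATTTATT\tCTATCCAAAATTCTAAAAAC\t143\t48"))
}

# deterministic synthetic genomic interior: no C except the CpGs and
# controls we place, so conversion controls and CpG offsets are exactly
# where intended and no accidental CpG arises
synth_interior <- function(len, n_cpgs, n_controls) {
  if (len < 3 * (n_cpgs + n_controls))
    stop("interior too short for requested CpG/control count")
  base <- sample(c("A", "T", "G"), len, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  slots <- round(seq(2, len - 2, length.out = n_cpgs + n_controls))
  which_cpg <- sort(sample(seq_along(slots), n_cpgs))
  for (i in seq_along(slots)) {
    s <- slots[i]
    base[s] <- "C"
    base[s + 1L] <- if (i %in% which_cpg) "G" else
      sample(c("A", "T"), 1L)
    if (s + 2L <= len && base[s + 2L] == "G" && base[s + 1L] == "C")
      base[s + 2L] <- "A"
  }
  # no accidental CpG: every C is placed, followed by G only when a CpG
  paste(base, collapse = "")
}

#' Build the packaged synthetic 16-marker panel
#'
#' Constructs, deterministically, a synthetic genomic region for each of
#' the 16 assays (real primer pairs, product lengths, coordinates and
#' annealing temperatures; synthetic interior sequence carrying 2–6 CpG
#' sites and 8–14 non-CpG cytosine conversion controls), runs
#' [in_silico_bisulfite_pcr()] on it and assembles the amplicon records
#' from the PCR product. The genomic regions are returned as an
#' attribute so tests can re-run the PCR against them.
#'
#' @param seed deterministic construction seed.
#' @return a `marker_panel` of 16 amplicons; attribute `genomic_regions`
#'   is a named character vector of the synthetic ±60 bp regions.
#' @export
build_synthetic_panel <- function(seed = 170205L) {
  assays <- panel16_assays()
  with_seed(seed, {
    regions <- character(0)
    amps <- vector("list", nrow(assays))
    for (i in seq_len(nrow(assays))) {
      a <- assays[i, ]
      interior_len <- a$len - nchar(a$fwd) - nchar(a$rev)
      n_cpgs <- sample(2:6, 1L)
      n_controls <- sample(8:14, 1L)
      repeat {
        interior <- synth_interior(interior_len, n_cpgs, n_controls)
        flank5 <- paste(sample(c("A", "T", "G"), 60, TRUE), collapse = "")
        flank3 <- paste(sample(c("A", "T", "G"), 60, TRUE), collapse = "")
        genomic <- paste0(flank5, a$fwd, interior, revcomp(a$rev), flank3)
        prod <- tryCatch(
          in_silico_bisulfite_pcr(genomic, a$fwd, a$rev),
          methage_multi_hit = function(e) NULL)
        # accept only a unique product of the designed length
        if (!is.null(prod) && prod$length == a$len) break
      }
      target <- prod$cpg_offsets[ceiling(length(prod$cpg_offsets) / 2)]
      amps[[i]] <- amplicon(
        a$cpg_id, a$gene, a$chrom, a$position, a$fwd, a$rev,
        prod$template_strand, prod$reference_seq, prod$cpg_offsets,
        target, prod$control_offsets, anneal_temp = a$tm,
        annotation = "synthetic reference sequence")
      regions[a$cpg_id] <- genomic
    }
    structure(marker_panel(amps), genomic_regions = regions)
  })
}

#' Load the packaged synthetic 16-marker panel
#'
#' Reads `inst/extdata/panel16_synthetic.json` (written by
#' [build_synthetic_panel()]); the reference sequences are synthetic,
#' the primers, product lengths, coordinates and annealing temperatures
#' are the published assay constants.
#'
#' @return a `marker_panel` of 16 amplicons.
#' @export
example_panel <- function() {
  path <- system.file("extdata", "panel16_synthetic.json",
                      package = "methage", mustWork = TRUE)
  load_panel(path)
}
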