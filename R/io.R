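# Readers and writers for the plain-text formats the pipeline touches.
#
# Conventions: all TSV and VCF coordinates are 1-based; BED output is
# 0-based half-open. Every writer states the convention in a header comment
# and writes atomically (the file is complete or untouched).

.gt_from_code <- c(ref_hom = "0/0", alt_hom = "1/1", het = "0/1",
                   missing = "./.")
.code_from_gt <- c(`0/0` = "ref_hom", `0|0` = "ref_hom",
                   `1/1` = "alt_hom", `1|1` = "alt_hom",
                   `0/1` = "het", `1/0` = "het", `0|1` = "het", `1|0` = "het",
                   `./.` = "missing", `.` = "missing")

#' Read a variant table (TSV or minimal VCF)
#'
#' The TSV layout is the one written by [write_variant_table()]: columns
#' `chrom, pos, ref, alt, p1_gt, p2_gt, p1_ref, p1_alt, p2_ref, p2_alt,
#' e_ref, e_alt, l_ref, l_alt`. VCF input must carry a per-sample `AD`
#' (ref,alt depths) field for the two parents and the two pools;
#' multi-allelic and indel records are skipped with a logged count. Parent
#' genotypes come from `GT` when present and are otherwise inferred from
#' the parent allele depths.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param samples Named character vector mapping the roles `p1`, `p2`, `e`,
#'   `l` to VCF sample names.
#' @return A variant-site data frame (see [sample_depths()]).
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf"),
                               samples = c(p1 = "P1", p2 = "P2",
                                           e = "E_pool", l = "L_pool")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    sites <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
    .check_site_table(sites)
    return(sites)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L & fix[, "ALT"] != "."
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("Skipped ", n_skipped, " multi-allelic or indel record(s)")
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    stop("VCF records lack the per-sample AD field", call. = FALSE)
  }
  missing_samples <- setdiff(samples, colnames(vcf@gt))
  if (length(missing_samples)) {
    stop("VCF lacks AD for sample(s): ", paste(missing_samples, collapse = ", "),
         call. = FALSE)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  split_ad <- function(sample) {
    parts <- strsplit(ifelse(is.na(ad[, sample]), "0,0", ad[, sample]), ",",
                      fixed = TRUE)
    list(ref = vapply(parts, function(p) as.integer(p[1]), integer(1)),
         alt = vapply(parts, function(p) as.integer(p[2]), integer(1)))
  }
  p1 <- split_ad(samples[["p1"]]); p2 <- split_ad(samples[["p2"]])
  ep <- split_ad(samples[["e"]]); lp <- split_ad(samples[["l"]])
  has_gt <- all(grepl("(^|:)GT(:|$)", fmt))
  gt_of <- function(sample, ref_d, alt_d) {
    if (has_gt) {
      g <- vcfR::extract.gt(vcf, element = "GT")[, sample]
      code <- unname(.code_from_gt[g])
      code[is.na(code)] <- "missing"
      code
    } else {
      ifelse(ref_d > 0 & alt_d == 0, "ref_hom",
             ifelse(alt_d > 0 & ref_d == 0, "alt_hom",
                    ifelse(ref_d > 0 & alt_d > 0, "het", "missing")))
    }
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    p1_gt = gt_of(samples[["p1"]], p1$ref, p1$alt),
    p2_gt = gt_of(samples[["p2"]], p2$ref, p2$alt),
    p1_ref = p1$ref, p1_alt = p1$alt,
    p2_ref = p2$ref, p2_alt = p2$alt,
    e_ref = ep$ref, e_alt = ep$alt,
    l_ref = lp$ref, l_alt = lp$alt,
    stringsAsFactors = FALSE)
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  .check_site_table(sites)
  sites
}

#' Write a variant table (TSV or minimal VCF 4.2)
#'
#' @param sites Variant-site data frame.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param samples Sample names used for the VCF columns.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(sites, path, format = c("auto", "tsv", "vcf"),
                                samples = c(p1 = "P1", p2 = "P2",
                                            e = "E_pool", l = "L_pool")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  .check_site_table(sites)
  if (format == "tsv") {
    return(write_atomic(path, function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines("# variant table; positions are 1-based", con)
      utils::write.table(sites, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }))
  }
  for (col in c("p1_ref", "p1_alt", "p2_ref", "p2_alt")) {
    if (!col %in% names(sites)) sites[[col]] <- 0L
  }
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
             paste(samples[c("p1", "p2", "e", "l")], collapse = "\t"))), con)
    fmt_sample <- function(gt, ref_d, alt_d) {
      sprintf("%s:%d,%d", gt, ref_d, alt_d)
    }
    lines <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s\t%s\t%s\t%s",
      sites$chrom, as.integer(sites$pos), sites$ref, sites$alt,
      fmt_sample(unname(.gt_from_code[sites$p1_gt]), sites$p1_ref, sites$p1_alt),
      fmt_sample(unname(.gt_from_code[sites$p2_gt]), sites$p2_ref, sites$p2_alt),
      fmt_sample("./.", sites$e_ref, sites$e_alt),
      fmt_sample("./.", sites$l_ref, sites$l_alt))
    writeLines(lines, con)
  })
}

#' Read / write QTL interval tables (Mb coordinates)
#'
#' Columns: `chrom`, `start_mb`, `end_mb`, `label`.
#' @param path File path.
#' @return `read_intervals()`: an interval data frame.
#' @export
read_intervals <- function(path) {
  iv <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start_mb", "end_mb") %in% names(iv)))
  if (!"label" %in% names(iv)) iv$label <- NA_character_
  iv
}

#' @param intervals Interval data frame.
#' @rdname read_intervals
#' @export
write_intervals <- function(intervals, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("# QTL intervals; Mb coordinates, 1-based inclusive endpoints", con)
    utils::write.table(intervals, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
}

#' Read / write a multi-variety genotype panel
#'
#' TSV with a `site` column followed by one column per variety; the
#' variety-to-group map is stored in a `#groups:` header comment.
#' @param path File path.
#' @return `read_panel()`: `list(calls =, groups =)`.
#' @export
read_panel <- function(path) {
  header <- readLines(path, n = 5L)
  gline <- grep("^#groups:", header, value = TRUE)
  if (length(gline) != 1L) stop("panel file lacks a '#groups:' header", call. = FALSE)
  pairs <- strsplit(strsplit(sub("^#groups:\\s*", "", gline), ",")[[1]], "=")
  groups <- stats::setNames(vapply(pairs, `[`, "", 2L),
                            vapply(pairs, `[`, "", 1L))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  list(calls = calls, groups = groups)
}

#' @param calls Sites x varieties call matrix.
#' @param groups Named variety-to-group map.
#' @rdname read_panel
#' @export
write_panel <- function(calls, groups, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste0("#groups: ",
                      paste(names(groups), groups, sep = "=", collapse = ",")),
               con)
    df <- data.frame(site = rownames(calls), calls, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Write a window profile as TSV
#'
#' @param profile Window profile from [window_scan()] / [add_null_band()].
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("# window profile; window_start 1-based, window_end exclusive", con)
    out <- profile
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Write called QTLs as TSV (1-based) and BED (0-based half-open)
#'
#' @param qtls QTL table from [call_qtls()].
#' @param path Output file; `format` defaults by extension.
#' @param format `"auto"`, `"tsv"` or `"bed"`.
#' @export
write_qtls <- function(qtls, path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (format == "tsv") {
      writeLines("# called QTL intervals; 1-based inclusive coordinates", con)
      utils::write.table(qtls, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      writeLines("# called QTL intervals; BED: 0-based half-open", con)
      if (nrow(qtls)) {
        bed <- data.frame(chrom = qtls$chrom,
                          start = format(qtls$start_bp - 1, scientific = FALSE,
                                         trim = TRUE),
                          end = format(qtls$end_bp, scientific = FALSE,
                                       trim = TRUE),
                          name = sprintf("qtl_%d", seq_len(nrow(qtls))),
                          score = 0L,
                          strand = ifelse(qtls$sign > 0, "+", "-"))
        utils::write.table(bed, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
      }
    }
  })
}

#' Read / write coding sequences as FASTA
#'
#' @param path File path.
#' @return `read_cds_fasta()`: a named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' @param seqs Named character vector (or named list) of DNA sequences.
#' @rdname read_cds_fasta
#' @export
write_cds_fasta <- function(seqs, path) {
  write_atomic(path, function(tmp) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(seqs)), tmp)
  })
}

#' Write phenotypes as TSV
#'
#' @param pop An [f2_population()].
#' @param path Output file.
#' @export
write_phenotypes <- function(pop, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("# days to first flowering per F2 individual", con)
    utils::write.table(
      data.frame(individual = seq_along(pop$phenotypes),
                 dff_days = signif(pop$phenotypes, 6)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
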