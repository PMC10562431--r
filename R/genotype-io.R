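#' Direct-to-consumer raw genotype parsing
#'
#' Consumer genealogy services let customers download their raw array calls
#' as a plain-text table keyed by rsID. Two dialects are supported:
#' the 23andMe-style layout (rsid, chromosome, position, genotype -- the
#' genotype given as a two-character string such as \code{"AT"}) and the
#' AncestryDNA-style layout (rsid, chromosome, position, allele1, allele2).
#' Header and comment lines start with \code{#}. Fields may be separated by
#' tabs or commas.
#'
#' Missing calls are encoded inconsistently across vendors; \code{"--"},
#' \code{"00"}, \code{"0"}, \code{"DD"}, \code{"II"}, and empty fields are
#' all read as missing. A single-allele (hemizygous) call is duplicated to a
#' homozygous pair; the diet-response panel is autosomal so this only
#' affects non-panel records.
#'
#' @param x Path to a raw export file, or a character vector of its lines.
#' @param dialect \code{"23andme"} or \code{"ancestry"}.
#' @param subject_id Identifier to attach to the parsed table.
#' @return A \code{genotype_table}: a list with elements \code{subject_id},
#'   \code{dialect}, and \code{calls}, a data frame with columns
#'   \code{rsid}, \code{chromosome}, \code{position}, \code{allele1},
#'   \code{allele2} (alleles are \code{NA} for missing calls).
#' @examples
#' txt <- c("# rsid\tchromosome\tposition\tgenotype",
#'          "rs9939609\t16\t53820527\tAT")
#' gt <- parse_dtc_table(txt, dialect = "23andme", subject_id = "S1")
#' gt$calls
#' @export
parse_dtc_table <- function(x, dialect = c("23andme", "ancestry"),
                            subject_id = "subject") {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }

  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_idx <- which(keep)
  want <- if (dialect == "23andme") 4L else 5L

  n <- length(data_idx)
  rsid <- chrom <- pos <- a1 <- a2 <- character(n)
  for (i in seq_len(n)) {
    line <- lines[data_idx[i]]
    sep <- if (grepl("\t", line, fixed = TRUE)) "\t" else ","
    f <- strsplit(line, sep, fixed = TRUE)[[1L]]
    if (length(f) != want) {
      stop(sprintf("malformed %s line %d: expected %d fields, found %d",
                   dialect, data_idx[i], want, length(f)), call. = FALSE)
    }
    f <- trimws(f)
    rsid[i] <- f[1L]; chrom[i] <- f[2L]; pos[i] <- f[3L]
    if (dialect == "23andme") {
      al <- .parse_genotype_string(f[4L])
    } else {
      al <- .parse_allele_pair(f[4L], f[5L])
    }
    a1[i] <- al[1L]; a2[i] <- al[2L]
  }

  calls <- data.frame(rsid = rsid, chromosome = chrom, position = pos,
                      allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  structure(list(subject_id = subject_id, dialect = dialect, calls = calls),
            class = "genotype_table")
}

.missing_sentinels <- c("--", "00", "0", "DD", "II", "", "-")

.parse_genotype_string <- function(g) {
  if (g %in% .missing_sentinels) return(c(NA_character_, NA_character_))
  ch <- strsplit(g, "")[[1L]]
  if (length(ch) == 1L) ch <- c(ch, ch)  # hemizygous call duplicated
  if (length(ch) != 2L || !all(ch %in% c("A", "C", "G", "T", "D", "I", "0", "-"))) {
    stop(sprintf("unrecognized genotype field '%s'", g), call. = FALSE)
  }
  if (any(ch %in% c("D", "I", "0", "-"))) return(c(NA_character_, NA_character_))
  sort(ch)
}

.parse_allele_pair <- function(x1, x2) {
  if (x1 %in% .missing_sentinels || x2 %in% .missing_sentinels) {
    return(c(NA_character_, NA_character_))
  }
  if (!all(c(x1, x2) %in% c("A", "C", "G", "T"))) {
    stop(sprintf("unrecognized allele fields '%s'/'%s'", x1, x2), call. = FALSE)
  }
  sort(c(x1, x2))
}

#' @export
print.genotype_table <- function(x, ...) {
  n_miss <- sum(is.na(x$calls$allele1))
  cat(sprintf("genotype_table: subject '%s', %d records (%d missing calls), %s dialect\n",
              x$subject_id, nrow(x$calls), n_miss, x$dialect))
  invisible(x)
}

#' Serialize a genotype table back to raw-export text
#'
#' Inverse of [parse_dtc_table()]: writing a table in either dialect and
#' re-parsing recovers the same calls.
#'
#' @param table A \code{genotype_table}.
#' @param dialect Target dialect, \code{"23andme"} or \code{"ancestry"}.
#' @return Character vector of file lines, including a comment header.
#' @export
write_dtc_table <- function(table, dialect = c("23andme", "ancestry")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "genotype_table"))
  cl <- table$calls
  if (dialect == "23andme") {
    geno <- ifelse(is.na(cl$allele1), "--", paste0(cl$allele1, cl$allele2))
    body <- paste(cl$rsid, cl$chromosome, cl$position, geno, sep = "\t")
    header <- "# rsid\tchromosome\tposition\tgenotype"
  } else {
    a1 <- ifelse(is.na(cl$allele1), "0", cl$allele1)
    a2 <- ifelse(is.na(cl$allele2), "0", cl$allele2)
    body <- paste(cl$rsid, cl$chromosome, cl$position, a1, a2, sep = "\t")
    header <- "# rsid\tchromosome\tposition\tallele1\tallele2"
  }
  c(header, body)
}

#' Extract the scoring panel from a genotype table
#'
#' Looks up each panel rsID in a subject's genotype table. Lookup is total:
#' rsIDs absent from the export come back as missing calls. A duplicated
#' rsID with identical calls is accepted silently; discordant duplicates are
#' a hard error (they indicate a corrupt export).
#'
#' @param table A \code{genotype_table}.
#' @param panel Data frame with at least a \code{rsid} column (e.g. the
#'   \code{panel} element of a [score_table]).
#' @return A data frame with one row per panel SNP (columns \code{rsid},
#'   \code{allele1}, \code{allele2}) and attribute \code{n_missing}.
#' @export
extract_panel <- function(table, panel) {
  stopifnot(inherits(table, "genotype_table"))
  rsids <- if (is.data.frame(panel)) panel$rsid else as.character(panel)
  if (length(rsids) == 0L) stop("panel is empty", call. = FALSE)
  if (anyDuplicated(rsids)) stop("duplicate rsid in panel", call. = FALSE)

  cl <- table$calls
  a1 <- rep(NA_character_, length(rsids))
  a2 <- rep(NA_character_, length(rsids))
  for (i in seq_along(rsids)) {
    hit <- which(cl$rsid == rsids[i])
    if (length(hit) == 0L) next
    g <- unique(paste(cl$allele1[hit], cl$allele2[hit]))
    if (length(g) > 1L) {
      stop(sprintf("discordant duplicate calls for %s in subject %s",
                   rsids[i], table$subject_id), call. = FALSE)
    }
    a1[i] <- cl$allele1[hit[1L]]
    a2[i] <- cl$allele2[hit[1L]]
  }
  out <- data.frame(rsid = rsids, allele1 = a1, allele2 = a2,
                    stringsAsFactors = FALSE)
  attr(out, "n_missing") <- sum(is.na(a1))
  attr(out, "subject_id") <- table$subject_id
  out
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Orient an observed allele pair onto a locus's reference alleles
#'
#' DTC arrays report calls on mixed strands. Given the two alleles expected
#' at a locus, an observed pair is accepted as-is if it is a subset of the
#' expected alleles, or complemented (and flagged \code{strand_flipped}) if
#' its Watson-Crick complement is. Strand-ambiguous loci -- those whose
#' expected allele pair is A/T or C/G, its own complement -- cannot be
#' disambiguated from the export alone; they are accepted as-is with
#' \code{ambiguous_strand = TRUE}.
#'
#' @param observed Character vector of two alleles.
#' @param snp List or one-row data frame with elements/columns
#'   \code{allele1} and \code{allele2}, the two expected alleles.
#' @return List with elements \code{alleles} (oriented pair, sorted),
#'   \code{strand_flipped}, and \code{ambiguous_strand}.
#' @export
normalize_alleles <- function(observed, snp) {
  ref <- c(as.character(snp$allele1), as.character(snp$allele2))
  stopifnot(length(ref) == 2L, all(ref %in% names(.complement)))
  observed <- as.character(observed)
  if (length(observed) != 2L || anyNA(observed)) {
    stop("observed genotype must be two non-missing alleles", call. = FALSE)
  }
  if (!all(observed %in% names(.complement))) {
    stop(sprintf("invalid alleles '%s'", paste(observed, collapse = "/")),
         call. = FALSE)
  }
  ambiguous <- setequal(ref, .complement[ref])
  if (ambiguous) {
    if (!all(observed %in% ref)) {
      stop(sprintf("alleles %s do not match expected %s",
                   paste(observed, collapse = "/"),
                   paste(ref, collapse = "/")), call. = FALSE)
    }
    return(list(alleles = sort(observed), strand_flipped = FALSE,
                ambiguous_strand = TRUE))
  }
  if (all(observed %in% ref)) {
    return(list(alleles = sort(observed), strand_flipped = FALSE,
                ambiguous_strand = FALSE))
  }
  comp <- unname(.complement[observed])
  if (all(comp %in% ref)) {
    return(list(alleles = sort(comp), strand_flipped = TRUE,
                ambiguous_strand = FALSE))
  }
  stop(sprintf("alleles %s match neither expected %s nor its complement",
               paste(observed, collapse = "/"), paste(ref, collapse = "/")),
       call. = FALSE)
}

#' Orient every non-missing call in an extracted panel
#'
#' Applies [normalize_alleles()] per panel SNP, leaving missing calls
#' missing.
#'
#' @param panel_genotypes Output of [extract_panel()].
#' @param panel Data frame with columns \code{rsid}, \code{allele1},
#'   \code{allele2} giving each locus's expected alleles.
#' @return \code{panel_genotypes} with alleles oriented and logical columns
#'   \code{strand_flipped} and \code{ambiguous_strand} added.
#' @export
normalize_panel <- function(panel_genotypes, panel) {
  pg <- panel_genotypes
  pg$strand_flipped <- FALSE
  pg$ambiguous_strand <- FALSE
  for (i in seq_len(nrow(pg))) {
    if (is.na(pg$allele1[i])) next
    def <- panel[panel$rsid == pg$rsid[i], , drop = FALSE]
    if (nrow(def) != 1L) {
      stop(sprintf("panel definition missing for %s", pg$rsid[i]),
           call. = FALSE)
    }
    nz <- normalize_alleles(c(pg$allele1[i], pg$allele2[i]), def)
    pg$allele1[i] <- nz$alleles[1L]
    pg$allele2[i] <- nz$alleles[2L]
    pg$strand_flipped[i] <- nz$strand_flipped
    pg$ambiguous_strand[i] <- nz$ambiguous_strand
  }
  pg
}
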