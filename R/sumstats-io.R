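## Reading, validating, harmonizing and writing GWAS summary-statistics
## tables and LD-score panels.

.DEFAULT_COLUMN_MAP <- c(variant_id = "variant_id", chrom = "chrom",
                         pos = "pos", effect_allele = "effect_allele",
                         other_allele = "other_allele", eaf = "eaf",
                         beta = "beta", se = "se", n = "n", info = "info")

.complementAllele <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

.isStrandAmbiguous <- function(ea, oa) {
  toupper(ea) == .complementAllele(toupper(oa))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited text file (gzip-transparent) with a
#' header line into a \linkS4class{SumstatsTable}. Rows that fail the type
#' or invariant checks (nonpositive SE, allele frequency outside (0,1),
#' identical alleles, nonpositive sample size, unparseable numerics) are
#' dropped and recorded with reason codes in the \code{droppedLog}
#' attribute of the returned object's variant data.
#'
#' @param path file path to the summary-statistics text file.
#' @param columnMap named character vector mapping the canonical column
#'   names (variant_id, chrom, pos, effect_allele, other_allele, eaf, beta,
#'   se, n, optionally info) to the column names present in the file.
#'   Canonical names absent from the map are assumed to appear verbatim.
#' @param phenotypeVariance variance of the analysed phenotype (1 for a
#'   standardized trait).
#' @param traitLabel label for the trait; defaults to the file name.
#'
#' @return a \linkS4class{SumstatsTable}; the per-row drop log is available
#'   via \code{attr(variantData(x), "droppedLog")}.
#' @export
readSumstats <- function(path, columnMap = character(),
                         phenotypeVariance = 1, traitLabel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  map <- .DEFAULT_COLUMN_MAP
  map[names(columnMap)] <- columnMap
  required <- setdiff(names(.DEFAULT_COLUMN_MAP), "info")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols))
    stop("required column(s) not found in ", path, ": ",
         paste(map[missing_cols], collapse = ", "),
         " (adjust columnMap)")
  v <- data.frame(variant_id = as.character(raw[[map["variant_id"]]]),
                  chrom = as.character(raw[[map["chrom"]]]),
                  pos = suppressWarnings(as.integer(raw[[map["pos"]]])),
                  effect_allele = toupper(as.character(raw[[map["effect_allele"]]])),
                  other_allele = toupper(as.character(raw[[map["other_allele"]]])),
                  eaf = suppressWarnings(as.numeric(raw[[map["eaf"]]])),
                  beta = suppressWarnings(as.numeric(raw[[map["beta"]]])),
                  se = suppressWarnings(as.numeric(raw[[map["se"]]])),
                  n = suppressWarnings(as.numeric(raw[[map["n"]]])),
                  stringsAsFactors = FALSE)
  if (map["info"] %in% names(raw))
    v$info <- suppressWarnings(as.numeric(raw[[map["info"]]]))

  reason <- rep(NA_character_, nrow(v))
  flag <- function(bad, code) ifelse(is.na(reason) & bad, code, reason)
  num_ok <- complete.cases(v[c("pos", "eaf", "beta", "se", "n")])
  reason <- flag(!num_ok, "unparseable")
  reason <- flag(v$se <= 0, "nonpositive se")
  reason <- flag(v$eaf <= 0 | v$eaf >= 1, "eaf out of (0,1)")
  reason <- flag(v$n <= 0, "nonpositive n")
  reason <- flag(v$effect_allele == v$other_allele, "identical alleles")
  reason <- flag(duplicated(v$variant_id), "duplicate id")
  keep <- is.na(reason)
  dropped <- data.frame(variant_id = v$variant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  v <- v[keep, , drop = FALSE]
  rownames(v) <- NULL
  if (nrow(v) == 0L) stop("no parseable rows in ", path)
  attr(v, "droppedLog") <- dropped
  new("SumstatsTable",
      traitLabel = if (is.null(traitLabel)) basename(path) else traitLabel,
      variants = v, phenotypeVariance = phenotypeVariance)
}

#' Write a summary-statistics table or harmonized set to text
#'
#' Tables are written tab-delimited with the fixed header variant_id,
#' chrom, pos, effect_allele, other_allele, eaf, beta_<label>, se_<label>,
#' p_<label>, n. For a \linkS4class{HarmonizedSet}, one beta/se/p/n block
#' per member table is emitted on the shared variant list.
#'
#' @param x a \linkS4class{SumstatsTable} or \linkS4class{HarmonizedSet}.
#' @param path output file path.
#' @return invisibly, the written data.frame.
#' @export
writeSumstats <- function(x, path) {
  block <- function(tab) {
    v <- variantData(tab)
    lab <- traitLabel(tab)
    p <- 2 * pnorm(-abs(v$beta / v$se))
    out <- data.frame(beta = v$beta, se = v$se, p = p, n = v$n)
    names(out) <- c(paste0("beta_", lab), paste0("se_", lab),
                    paste0("p_", lab), paste0("n_", lab))
    out
  }
  if (is(x, "SumstatsTable")) {
    v <- variantData(x)
    out <- cbind(v[c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf")], block(x))
    names(out)[names(out) == paste0("n_", traitLabel(x))] <- "n"
  } else if (is(x, "HarmonizedSet")) {
    tabs <- harmonizedTables(x)
    v <- variantData(tabs[[1]])
    out <- cbind(v[c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf")],
                 do.call(cbind, lapply(tabs, block)))
  } else stop("writeSumstats needs a SumstatsTable or HarmonizedSet")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read an LD-score panel
#'
#' Delimited text with a header; the first two columns (or columns named
#' variant_id / ld_score) give the variant and its LD score, an optional
#' third column gives a regression weight.
#'
#' @param path file path.
#' @param mSnps genome-wide number of variants M underlying the LD scores;
#'   defaults to the number of rows in the panel.
#' @return an \linkS4class{LDScorePanel}.
#' @export
readLDScorePanel <- function(path, mSnps = NULL) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "ld_score") %in% names(raw))) {
    names(raw)[1:2] <- c("variant_id", "ld_score")
    if (ncol(raw) >= 3L) names(raw)[3] <- "weight"
  }
  sc <- data.frame(variant_id = as.character(raw$variant_id),
                   ld_score = as.numeric(raw$ld_score),
                   stringsAsFactors = FALSE)
  if ("weight" %in% names(raw)) sc$weight <- as.numeric(raw$weight)
  new("LDScorePanel", scores = sc,
      mSnps = if (is.null(mSnps)) nrow(sc) else mSnps)
}

#' Harmonize two or more summary-statistics tables
#'
#' Restricts all tables to the shared variant list and aligns their effect
#' alleles to the first table. Where allele labels are swapped relative to
#' the reference table the beta sign is flipped and the allele frequency
#' replaced by 1 - eaf; when \code{dropStrandAmbiguous} is FALSE, variants
#' whose alleles match only after strand complementation are reconciled the
#' same way. Irreconcilable allele pairs are dropped, as are variants with
#' min(eaf, 1-eaf) below \code{mafMin} in any table, variants whose aligned
#' allele frequencies disagree by more than 0.2 between tables, and (when
#' requested) strand-ambiguous A/T and C/G variants.
#'
#' @param tables list of \linkS4class{SumstatsTable} (>= 2). Names become
#'   the table labels; unnamed lists use each table's traitLabel.
#' @param mafMin minimum minor allele frequency; variants below it in any
#'   table are removed. The SEM pathway conventionally uses 0.005; the
#'   linear and overlap-aware pathways use 0.
#' @param dropStrandAmbiguous drop A/T and C/G variants instead of
#'   attempting strand reconciliation.
#' @return a \linkS4class{HarmonizedSet}.
#' @export
harmonizeSumstats <- function(tables, mafMin = 0, dropStrandAmbiguous = FALSE) {
  if (length(tables) < 2L) stop("harmonization needs at least two tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, traitLabel, "")
  ref <- variantData(tables[[1]])
  ids <- ref$variant_id
  for (t in tables[-1]) ids <- intersect(ids, variantData(t)$variant_id)
  if (length(ids) == 0L) stop("no variants shared by all tables")

  logged <- data.frame(variant_id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  note <- function(id, code) {
    if (length(id))
      logged <<- rbind(logged, data.frame(variant_id = id, reason = code,
                                          stringsAsFactors = FALSE))
  }
  note(setdiff(ref$variant_id, ids), "absent in another table")

  aligned <- lapply(tables, function(t) {
    v <- variantData(t)
    v[match(ids, v$variant_id), , drop = FALSE]
  })
  refv <- aligned[[1]]
  drop <- rep(FALSE, length(ids))
  reason <- rep(NA_character_, length(ids))
  mark <- function(bad, code) {
    fresh <- bad & !drop
    drop <<- drop | bad
    reason[fresh] <<- code
  }

  if (dropStrandAmbiguous)
    mark(.isStrandAmbiguous(refv$effect_allele, refv$other_allele),
         "strand ambiguous")

  for (k in seq_along(aligned)[-1]) {
    v <- aligned[[k]]
    same <- v$effect_allele == refv$effect_allele &
            v$other_allele == refv$other_allele
    swap <- v$effect_allele == refv$other_allele &
            v$other_allele == refv$effect_allele
    if (!dropStrandAmbiguous) {
      # strand reconciliation only when alleles complement exactly
      cea <- .complementAllele(v$effect_allele)
      coa <- .complementAllele(v$other_allele)
      same <- same | (cea == refv$effect_allele & coa == refv$other_allele)
      swap <- swap | (!same & cea == refv$other_allele & coa == refv$effect_allele)
    }
    mark(!(same | swap), "allele mismatch")
    v$beta[swap] <- -v$beta[swap]
    v$eaf[swap] <- 1 - v$eaf[swap]
    v$effect_allele <- refv$effect_allele
    v$other_allele <- refv$other_allele
    if (any(ok <- !drop)) {
      if (any(v$chrom[ok] != refv$chrom[ok] | v$pos[ok] != refv$pos[ok]))
        warning("chrom/pos disagree across tables for some shared variant IDs; ",
                "positions from the first table are used")
    }
    mark(abs(v$eaf - refv$eaf) > 0.2, "eaf mismatch")
    aligned[[k]] <- v
  }
  if (mafMin > 0) {
    maf_low <- Reduce(`|`, lapply(aligned, function(v) pmin(v$eaf, 1 - v$eaf) < mafMin))
    mark(maf_low, "maf")
  }
  note(ids[drop], reason[drop])
  if (all(drop)) stop("no variants left after harmonization")

  out <- mapply(function(t, v) {
    v <- v[!drop, , drop = FALSE]
    rownames(v) <- NULL
    attr(v, "droppedLog") <- NULL
    initialize(t, variants = v)
  }, tables, aligned, SIMPLIFY = FALSE)
  new("HarmonizedSet", tables = out, droppedLog = logged)
}

## matrix views over a harmonized set (variants x tables)
.hsMatrix <- function(hs, field) {
  do.call(cbind, lapply(harmonizedTables(hs),
                        function(t) variantData(t)[[field]]))
}

#' Matrix views over a HarmonizedSet
#'
#' Convenience extractors returning nVariants x K matrices of betas,
#' standard errors or z-scores (beta/se), and median per-table sample sizes.
#'
#' @param hs a \linkS4class{HarmonizedSet}.
#' @return a numeric matrix (or vector for \code{sampleSizes}) with one
#'   column (element) per member table.
#' @export
betaMatrix <- function(hs) .hsMatrix(hs, "beta")

#' @rdname betaMatrix
#' @export
seMatrix <- function(hs) .hsMatrix(hs, "se")

#' @rdname betaMatrix
#' @export
zMatrix <- function(hs) betaMatrix(hs) / seMatrix(hs)

#' @rdname betaMatrix
#' @export
sampleSizes <- function(hs)
  vapply(harmonizedTables(hs), function(t) median(variantData(t)$n), 1)

## align an LD panel to a harmonized set, in variant order
.alignPanel <- function(hs, ld) {
  ids <- variantData(harmonizedTables(hs)[[1]])$variant_id
  sc <- ldScores(ld)
  idx <- match(ids, sc$variant_id)
  if (anyNA(idx)) stop(sum(is.na(idx)), " harmonized variants missing from the LD panel")
  sc[idx, , drop = FALSE]
}
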