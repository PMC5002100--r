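#' Quality-control report
#'
#' Bookkeeping object for [apply_qc()].  Removal categories are applied
#' disjointly in a fixed order (each SNP is counted in the first matching
#' category), so `retained + sum(removed)` always equals the input total.
#'
#' @param total input SNP count.
#' @param removed named numeric vector of removed counts with names
#'   `excluded_chrom`, `mendel`, `ungenotyped`, `monomorphic`,
#'   `low_call_rate` (missing categories default to 0).
#' @param disposition optional per-SNP factor of category assignments.
#' @return An object of class `qc_report` with a computed `retained` count.
#' @export
qc_report <- function(total, removed, disposition = NULL) {
  cats <- c("excluded_chrom", "mendel", "ungenotyped", "monomorphic",
            "low_call_rate")
  full <- setNames(numeric(length(cats)), cats)
  full[names(removed)] <- removed
  if (any(full < 0) || total < sum(full))
    stop("inconsistent QC counts: removals exceed the input total")
  structure(
    list(total = total, removed = full, retained = total - sum(full),
         disposition = disposition),
    class = "qc_report"
  )
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("SNP quality control:", x$total, "input SNPs\n")
  for (k in names(x$removed))
    cat(sprintf("  removed %-15s %d\n", k, as.integer(x$removed[k])))
  cat("  retained:", x$retained, "\n")
  invisible(x)
}

# Mendelian consistency of a child genotype (0/1/2 dosage) given both
# parents: child dosage must be a feasible sum of one gamete from each.
.trio_ok_table <- local({
  gam <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  ok <- array(FALSE, dim = c(3, 3, 3))  # [child+1, p1+1, p2+1]
  for (p1 in 0:2) for (p2 in 0:2) {
    feasible <- unique(outer(gam[[p1 + 1]], gam[[p2 + 1]], `+`))
    for (c_ in 0:2) ok[c_ + 1, p1 + 1, p2 + 1] <- c_ %in% feasible
  }
  ok
})

#' Per-SNP Mendelian-error rate
#'
#' For every SNP, counts parent-offspring checks that are impossible under
#' Mendelian inheritance.  A "check" is one child scored against its
#' genotyped parents at one SNP: a trio check when both parents are
#' genotyped there (child dosage must be reachable by one gamete from each
#' parent), a duo check when exactly one is (opposite homozygotes are
#' impossible).  The rate is violations / checks; SNPs with no checks get
#' rate 0 and are flagged.
#'
#' @param ds a [genotype_dataset()].
#' @param ped pedigree data frame (`child`, `sire`, `dam`; `NA` = unknown).
#' @return Data frame with per-SNP `id`, `n_checks`, `n_violations`, `rate`
#'   and `no_checks` flag.
#' @export
mendel_error_rate <- function(ds, ped) {
  if (is.null(ped) || nrow(ped) == 0)
    stop("empty pedigree: skip the Mendelian filter instead")
  samples <- rownames(ds$a1)
  ped <- ped[ped$child %in% samples, , drop = FALSE]
  ped$sire[!(ped$sire %in% samples)] <- NA
  ped$dam[!(ped$dam %in% samples)] <- NA
  ped <- ped[!is.na(ped$sire) | !is.na(ped$dam), , drop = FALSE]
  if (nrow(ped) == 0)
    stop("pedigree contains no child with a genotyped parent")

  G <- ds$a1 + ds$a2  # dosage; NA if any allele missing
  M <- ncol(G)
  idx <- function(id) ifelse(is.na(id), NA_integer_, match(id, samples))
  gc_ <- G[idx(ped$child), , drop = FALSE]
  gs <- matrix(NA_integer_, nrow(ped), M)
  gd <- matrix(NA_integer_, nrow(ped), M)
  has_s <- !is.na(ped$sire)
  has_d <- !is.na(ped$dam)
  gs[has_s, ] <- G[idx(ped$sire[has_s]), , drop = FALSE]
  gd[has_d, ] <- G[idx(ped$dam[has_d]), , drop = FALSE]

  child_ok <- !is.na(gc_)
  trio <- child_ok & !is.na(gs) & !is.na(gd)
  duo_s <- child_ok & !is.na(gs) & is.na(gd)
  duo_d <- child_ok & is.na(gs) & !is.na(gd)

  viol <- matrix(FALSE, nrow(ped), M)
  if (any(trio)) {
    flat <- gc_[trio] + 3L * gs[trio] + 9L * gd[trio] + 1L
    viol[trio] <- !.trio_ok_table[flat]
  }
  duo_bad <- function(p, c_) (p == 0L & c_ == 2L) | (p == 2L & c_ == 0L)
  viol[duo_s] <- duo_bad(gs[duo_s], gc_[duo_s])
  viol[duo_d] <- duo_bad(gd[duo_d], gc_[duo_d])

  checks <- colSums(trio) + colSums(duo_s) + colSums(duo_d)
  nviol <- colSums(viol)
  data.frame(
    id = ds$markers$id,
    n_checks = checks,
    n_violations = nviol,
    rate = ifelse(checks > 0, nviol / checks, 0),
    no_checks = checks == 0,
    stringsAsFactors = FALSE
  )
}

#' Apply SNP quality control
#'
#' Removes SNPs in a fixed category order, each SNP attributed to the first
#' matching category: (1) unplaced or excluded chromosomes, (2) Mendelian
#' inconsistency above `mendel_max` (skipped with a warning when no pedigree
#' is supplied), (3) fully ungenotyped SNPs, (4) SNPs monomorphic in the
#' pooled sample across all lines, (5) genotype call rate below
#' `call_rate_min` (computed over all samples pooled).
#'
#' @param ds a [genotype_dataset()].
#' @param ped optional pedigree for the Mendelian filter.
#' @param call_rate_min minimum genotype call rate (default 0.90).
#' @param mendel_max maximum tolerated Mendelian-error rate (default 0.001).
#' @param excluded_chroms chromosome labels to drop outright.
#' @return A list with the filtered `ds` and a `report` ([qc_report()]).
#' @export
apply_qc <- function(ds, ped = NULL, call_rate_min = 0.90,
                     mendel_max = 0.001, excluded_chroms = character()) {
  if (nrow(ds$markers) == 0) stop("empty dataset")
  unknown <- setdiff(excluded_chroms, unique(ds$markers$chrom))
  if (length(unknown) > 0)
    warning("excluded chromosome label(s) not present in the data: ",
            paste(unknown, collapse = ", "))

  M <- nrow(ds$markers)
  disp <- rep("retained", M)

  is_excl <- ds$markers$chrom %in% excluded_chroms | is.na(ds$markers$bp)

  if (is.null(ped)) {
    warning("no pedigree supplied: Mendelian-inconsistency filter skipped")
    is_mendel <- rep(FALSE, M)
  } else {
    mr <- mendel_error_rate(ds, ped)
    is_mendel <- mr$rate > mendel_max
  }

  called <- !is.na(ds$a1) & !is.na(ds$a2)
  n_called <- colSums(called)
  is_ungeno <- n_called == 0

  n1 <- colSums(ds$a1 == 1L, na.rm = TRUE) + colSums(ds$a2 == 1L, na.rm = TRUE)
  n_al <- colSums(!is.na(ds$a1)) + colSums(!is.na(ds$a2))
  is_mono <- n_al > 0 & (n1 == 0 | n1 == n_al)

  is_lcr <- n_called / nrow(ds$a1) < call_rate_min

  disp[is_lcr] <- "low_call_rate"
  disp[is_mono] <- "monomorphic"
  disp[is_ungeno] <- "ungenotyped"
  disp[is_mendel] <- "mendel"
  disp[is_excl] <- "excluded_chrom"

  disp <- factor(disp, levels = c("retained", "excluded_chrom", "mendel",
                                  "ungenotyped", "monomorphic",
                                  "low_call_rate"))
  keep <- disp == "retained"
  if (!any(keep)) stop("quality control removed every SNP")
  removed <- table(disp)[-1]
  report <- qc_report(M, setNames(as.numeric(removed), names(removed)),
                      disposition = disp)
  list(ds = gt_subset(ds, markers = which(keep)), report = report)
}

#' Write a QC report (per-SNP TSV + JSON summary)
#' @param report a [qc_report()].
#' @param ds the input dataset the report refers to (for SNP IDs).
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return Invisibly, `report`.
#' @export
write_qc_report <- function(report, ds = NULL, tsv = NULL, json = NULL) {
  if (!is.null(tsv) && !is.null(report$disposition) && !is.null(ds)) {
    write.table(
      data.frame(id = ds$markers$id, disposition = report$disposition),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(total = report$total, removed = as.list(report$removed),
           retained = report$retained),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Naive within-line genotype imputation
#'
#' Fills each missing allele with a Bernoulli draw from the within-line
#' allele frequency at that SNP (falling back to the pooled frequency when a
#' line has no observed call there).  This is a deliberately simple stand-in
#' for statistical phasing/imputation and preserves the dataset's phase
#' flag: it never creates phase information.
#'
#' @param ds a [genotype_dataset()].
#' @param seed integer seed; imputation is deterministic given it.
#' @return The dataset with no missing alleles.
#' @export
naive_impute <- function(ds, seed) {
  set.seed(seed)
  a1 <- ds$a1
  a2 <- ds$a2
  pool <- pooled_freq(ds)
  pool[is.na(pool)] <- 0.5
  n_pool_fallback <- 0L
  for (l in unique(ds$lines)) {
    idx <- which(ds$lines == l)
    s1 <- a1[idx, , drop = FALSE]
    s2 <- a2[idx, , drop = FALSE]
    n1 <- colSums(s1 == 1L, na.rm = TRUE) + colSums(s2 == 1L, na.rm = TRUE)
    n <- colSums(!is.na(s1)) + colSums(!is.na(s2))
    f <- ifelse(n > 0, n1 / n, NA_real_)
    fallback <- is.na(f)
    n_pool_fallback <- n_pool_fallback + sum(fallback)
    f[fallback] <- pool[fallback]
    for (mat in c("s1", "s2")) {
      m <- get(mat)
      miss <- which(is.na(m), arr.ind = TRUE)
      if (nrow(miss) > 0)
        m[miss] <- rbinom(nrow(miss), 1L, f[miss[, 2]])
      assign(mat, m)
    }
    a1[idx, ] <- s1
    a2[idx, ] <- s2
  }
  if (n_pool_fallback > 0)
    message(n_pool_fallback,
            " line-by-SNP cell(s) imputed from the pooled frequency")
  genotype_dataset(a1, a2, ds$markers, ds$lines, phased = ds$phased,
                  alleles = ds$alleles)
}
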