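#' Cross-tabulated births and cases by maternal and paternal age
#'
#' Constructs and validates the central data container: a J x K table of
#' total births `n[j,k]` and case counts `Y[j,k]` indexed by single-year
#' maternal ages (rows) and paternal ages (columns).  Ages are integer years
#' and must be contiguous; the conventional grid is maternal 15-49 (J = 35)
#' by paternal 15-65 (K = 51).
#'
#' @param maternal_ages integer vector of maternal ages, strictly increasing
#'   in steps of 1.
#' @param paternal_ages integer vector of paternal ages, strictly increasing
#'   in steps of 1.
#' @param births J x K matrix of non-negative integer birth counts.
#' @param cases J x K matrix of non-negative integer case counts, cell-wise
#'   no greater than `births`.
#' @param outcome short text label for the outcome (e.g. `"DS"`).
#' @return an object of class `age_crosstab`: a list with elements
#'   `maternal_ages`, `paternal_ages`, `births`, `cases`, `outcome`.
#' @seealso [read_crosstab()], [marginalize()], [simulate_crosstab()]
#' @examples
#' tab <- age_crosstab(15:17, 15:18,
#'                     births = matrix(100, 3, 4),
#'                     cases  = matrix(1, 3, 4), outcome = "toy")
#' tab
#' @export
age_crosstab <- function(maternal_ages, paternal_ages, births, cases,
                         outcome = "outcome") {
  births <- as.matrix(births)
  cases <- as.matrix(cases)
  if (is.numeric(births)) births <- as_count(births)
  if (is.numeric(cases)) cases <- as_count(cases)
  obj <- structure(list(maternal_ages = as.integer(maternal_ages),
                        paternal_ages = as.integer(paternal_ages),
                        births = births, cases = cases,
                        outcome = as.character(outcome)[1]),
                   class = "age_crosstab")
  validate_crosstab(obj)
  dimnames(obj$births) <- dimnames(obj$cases) <-
    list(maternal = obj$maternal_ages, paternal = obj$paternal_ages)
  obj
}

# store whole-valued counts as integers so round-trips are exact
as_count <- function(x) {
  if (all(is.finite(x)) && all(x == floor(x)) && all(abs(x) < 2^31 - 1))
    storage.mode(x) <- "integer"
  x
}

check_age_vector <- function(ages, what) {
  if (length(ages) < 1 || anyNA(ages))
    stop(what, " ages must be non-missing integers")
  if (length(ages) > 1 && any(diff(ages) != 1L))
    stop(what, " ages must be strictly increasing in steps of 1 year")
  invisible(ages)
}

check_counts <- function(births, cases, cell_label) {
  bad <- which(!is.finite(births) | births < 0 | births != floor(births))
  if (length(bad))
    stop("births must be non-negative integers; first offending cell: ",
         cell_label(bad[1]))
  bad <- which(!is.finite(cases) | cases < 0 | cases != floor(cases))
  if (length(bad))
    stop("cases must be non-negative integers; first offending cell: ",
         cell_label(bad[1]))
  bad <- which(cases > births)
  if (length(bad))
    stop("cases exceed births; first offending cell: ", cell_label(bad[1]),
         " (cases=", cases[bad[1]], ", births=", births[bad[1]], ")")
  invisible(NULL)
}

validate_crosstab <- function(tab) {
  check_age_vector(tab$maternal_ages, "maternal")
  check_age_vector(tab$paternal_ages, "paternal")
  J <- length(tab$maternal_ages); K <- length(tab$paternal_ages)
  if (!identical(dim(tab$births), c(J, K)) ||
      !identical(dim(tab$cases), c(J, K)))
    stop("births and cases must be ", J, " x ", K,
         " matrices matching the declared age vectors")
  lab <- function(i) {
    j <- ((i - 1) %% J) + 1; k <- ((i - 1) %/% J) + 1
    paste0("(maternal ", tab$maternal_ages[j],
           ", paternal ", tab$paternal_ages[k], ")")
  }
  check_counts(tab$births, tab$cases, lab)
  invisible(tab)
}

#' @export
print.age_crosstab <- function(x, ...) {
  cat("Age cross-tabulation [", x$outcome, "]: ",
      length(x$maternal_ages), " maternal ages (",
      min(x$maternal_ages), "-", max(x$maternal_ages), ") x ",
      length(x$paternal_ages), " paternal ages (",
      min(x$paternal_ages), "-", max(x$paternal_ages), ")\n", sep = "")
  cat("  births: ", format(sum(x$births), big.mark = ","),
      "   cases: ", format(sum(x$cases), big.mark = ","),
      "   crude prevalence: ",
      signif(sum(x$cases) / max(1, sum(x$births)) * 1e4, 3),
      " per 10,000\n", sep = "")
  invisible(x)
}

#' Marginal (single-parent) count table
#'
#' @param ages contiguous integer ages.
#' @param births,cases non-negative integer vectors along `ages`.
#' @param parent `"maternal"` or `"paternal"`.
#' @param outcome outcome label.
#' @return object of class `age_margin`.
#' @export
age_margin <- function(ages, births, cases, parent = c("maternal", "paternal"),
                       outcome = "outcome") {
  parent <- match.arg(parent)
  ages <- check_age_vector(as.integer(ages), parent)
  births <- as.numeric(births); cases <- as.numeric(cases)
  if (length(births) != length(ages) || length(cases) != length(ages))
    stop("births and cases must have one entry per age")
  check_counts(births, cases,
               function(i) paste0("(", parent, " ", ages[i], ")"))
  births <- as_count(births); cases <- as_count(cases)
  structure(list(ages = ages, births = births, cases = cases,
                 parent = parent, outcome = as.character(outcome)[1]),
            class = "age_margin")
}

#' @export
print.age_margin <- function(x, ...) {
  cat("Marginal ", x$parent, "-age table [", x$outcome, "]: ages ",
      min(x$ages), "-", max(x$ages), ", births ",
      format(sum(x$births), big.mark = ","), ", cases ",
      format(sum(x$cases), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Collapse a cross-tabulation over one parent's axis
#'
#' Sums births and cases over the other parent's ages, producing the marginal
#' table used by the single-parent (unadjusted) models.  Grand totals are
#' conserved exactly.
#'
#' @param tab an [age_crosstab()].
#' @param parent which parent's axis to keep: `"maternal"` or `"paternal"`.
#' @return an [age_margin()].
#' @examples
#' tab <- age_crosstab(15:16, 15:17, matrix(10, 2, 3), matrix(1, 2, 3))
#' marginalize(tab, "paternal")
#' @export
marginalize <- function(tab, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  stopifnot(inherits(tab, "age_crosstab"))
  if (parent == "maternal")
    age_margin(tab$maternal_ages, rowSums(tab$births), rowSums(tab$cases),
               "maternal", tab$outcome)
  else
    age_margin(tab$paternal_ages, colSums(tab$births), colSums(tab$cases),
               "paternal", tab$outcome)
}

#' Read a cross-tabulation from disk
#'
#' Two formats are supported. `"csv"` is the canonical long format: a header
#' row then one row per cell with columns `maternal_age, paternal_age,
#' births, cases`.  `"bugs_rectangular"` reads (read-only) the BUGS-style
#' data block `list(Y = structure(.Data = c(...), .Dim = c(J, K)), n =
#' structure(...))`; `.Data` is taken in BUGS/S-PLUS row-major order.  For
#' marginal BUGS files `Y` and `n` may be plain `c(...)` vectors, in which
#' case a one-column table is returned spanning `maternal_ages`.
#'
#' Malformed input is rejected, never repaired: missing cells inside the age
#' rectangle are an error unless `allow_sparse = TRUE` (then treated as
#' births = 0, cases = 0), and any cell with `cases > births`, negative or
#' fractional counts, or duplicated coordinates names the offending cell.
#'
#' @param path file path.
#' @param format `"csv"` or `"bugs_rectangular"`.
#' @param maternal_ages,paternal_ages declared age ranges; `NULL` (default)
#'   infers the contiguous range spanned by the data.
#' @param allow_sparse zero-fill cells absent from a CSV inside the declared
#'   rectangle instead of erroring.
#' @param outcome outcome label attached to the result.
#' @return an [age_crosstab()].
#' @export
read_crosstab <- function(path, format = c("csv", "bugs_rectangular"),
                          maternal_ages = NULL, paternal_ages = NULL,
                          allow_sparse = FALSE, outcome = "outcome") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv")
    read_crosstab_csv(path, maternal_ages, paternal_ages, allow_sparse,
                      outcome)
  else
    read_crosstab_bugs(path, maternal_ages, paternal_ages, outcome)
}

read_crosstab_csv <- function(path, maternal_ages, paternal_ages,
                              allow_sparse, outcome) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("maternal_age", "paternal_age", "births", "cases")
  if (!all(need %in% names(d)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(d) == 0) stop("empty table in ", path)
  if (anyNA(d[need])) stop("missing values in ", path)
  if (is.null(maternal_ages))
    maternal_ages <- seq(min(d$maternal_age), max(d$maternal_age))
  if (is.null(paternal_ages))
    paternal_ages <- seq(min(d$paternal_age), max(d$paternal_age))
  j <- match(d$maternal_age, maternal_ages)
  k <- match(d$paternal_age, paternal_ages)
  if (anyNA(j) || anyNA(k)) {
    bad <- which(is.na(j) | is.na(k))[1]
    stop("age pair outside the declared rectangle: (maternal ",
         d$maternal_age[bad], ", paternal ", d$paternal_age[bad], ")")
  }
  idx <- cbind(j, k)
  if (anyDuplicated(idx)) {
    bad <- idx[which(duplicated(idx))[1], ]
    stop("duplicated cell: (maternal ", maternal_ages[bad[1]],
         ", paternal ", paternal_ages[bad[2]], ")")
  }
  J <- length(maternal_ages); K <- length(paternal_ages)
  if (nrow(d) < J * K && !allow_sparse) {
    all_jk <- expand.grid(j = seq_len(J), k = seq_len(K))
    miss <- !(paste(all_jk$j, all_jk$k) %in% paste(j, k))
    m1 <- all_jk[which(miss)[1], ]
    stop("missing cell (maternal ", maternal_ages[m1$j], ", paternal ",
         paternal_ages[m1$k], "); pass allow_sparse = TRUE to zero-fill")
  }
  births <- matrix(0, J, K); cases <- matrix(0, J, K)
  births[idx] <- d$births
  cases[idx] <- d$cases
  age_crosstab(maternal_ages, paternal_ages, births, cases, outcome)
}

# pull "name = structure(.Data = c(...), .Dim = c(...))" or "name = c(...)"
# out of a BUGS data block
bugs_extract <- function(txt, name) {
  pat <- paste0("\\b", name,
                "\\s*=\\s*structure\\(\\s*\\.Data\\s*=\\s*c\\(([^)]*)\\)\\s*,",
                "\\s*\\.Dim\\s*=\\s*c\\(([^)]*)\\)")
  m <- regmatches(txt, regexec(pat, txt))[[1]]
  if (length(m) == 3) {
    vals <- as.numeric(strsplit(m[2], ",")[[1]])
    dims <- as.integer(as.numeric(strsplit(m[3], ",")[[1]]))
    return(list(data = vals, dim = dims))
  }
  pat <- paste0("\\b", name, "\\s*=\\s*c\\(([^)]*)\\)")
  m <- regmatches(txt, regexec(pat, txt))[[1]]
  if (length(m) == 2)
    return(list(data = as.numeric(strsplit(m[2], ",")[[1]]), dim = NULL))
  stop("variable '", name, "' not found in BUGS data block")
}

read_crosstab_bugs <- function(path, maternal_ages, paternal_ages, outcome) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  Y <- bugs_extract(txt, "Y")
  n <- bugs_extract(txt, "n")
  if (is.null(maternal_ages)) maternal_ages <- 15:49
  if (is.null(paternal_ages)) paternal_ages <- 15:65
  if (!is.null(Y$dim)) {
    J <- Y$dim[1]; K <- Y$dim[2]
    if (J != length(maternal_ages) || K != length(paternal_ages))
      stop(".Dim c(", J, ",", K, ") does not match the declared age ranges")
    # BUGS .Data is row-major
    cases <- matrix(Y$data, J, K, byrow = TRUE)
    births <- matrix(n$data, J, K, byrow = TRUE)
    age_crosstab(maternal_ages, paternal_ages, births, cases, outcome)
  } else {
    L <- length(Y$data)
    ages <- if (L == length(maternal_ages)) maternal_ages else paternal_ages
    if (L != length(ages))
      stop("vector length ", L, " matches neither declared age range")
    parent <- if (L == length(maternal_ages)) "maternal" else "paternal"
    age_margin(ages, n$data, Y$data, parent, outcome)
  }
}

#' Write a cross-tabulation to CSV
#'
#' Writes the canonical long format (`maternal_age, paternal_age, births,
#' cases`, one row per cell including empty cells) so that
#' `read_crosstab(write_crosstab(tab))` is the identity.
#'
#' @param tab an [age_crosstab()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(tab, path) {
  stopifnot(inherits(tab, "age_crosstab"))
  d <- data.frame(
    maternal_age = rep(tab$maternal_ages, times = length(tab$paternal_ages)),
    paternal_age = rep(tab$paternal_ages, each = length(tab$maternal_ages)),
    births = as.vector(tab$births),
    cases = as.vector(tab$cases))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
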