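#' @keywords internal
"_PACKAGE"

# Derive a child seed from a master seed and a small stage index.
# Kept below 2^31 - 1 so set.seed() always accepts it.
sub_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stage) * 10007) %% 2147483629L) + 1L
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user-level streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stratified k-fold assignment: returns an integer fold id per observation,
# guaranteeing every class appears in every fold where feasible.
stratified_folds <- function(y, k, seed = NULL) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("stratified folding impossible: a class has fewer than ", k, " members")
  }
  assign_one <- function(idx) {
    idx <- sample(idx)
    rep_len(seq_len(k), length(idx))[order(order(idx))] # balanced split
  }
  folds <- integer(length(y))
  run <- function() {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      idx <- sample(idx)
      folds[idx] <<- rep_len(seq_len(k), length(idx))
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  folds
}

# Stratified train-subset indices: a fraction `p` of each class.
stratified_subsample <- function(y, p, seed = NULL) {
  y <- as.factor(y)
  draw <- function() {
    unlist(lapply(levels(y), function(lev) {
      idx <- which(y == lev)
      sample(idx, max(1L, round(p * length(idx))))
    }), use.names = FALSE)
  }
  if (is.null(seed)) sort(draw()) else sort(with_seed(seed, draw()))
}

# Validate a genes-by-samples expression matrix and return it with dimnames.
as_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(expr))) stop("sample identifiers must be unique")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  expr
}

# Check requested genes exist in the matrix; error listing the absent ones.
check_genes_present <- function(expr, genes) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("genes absent from expression matrix: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
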