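#' Per-region means of a parameter map
#'
#' @param map 3D numeric array (NA treated as missing).
#' @param labels 3D integer array of region labels on the same grid; 0 (or
#'   NA) marks voxels outside every region.
#' @return named numeric vector of per-label means; a label requested via the
#'   factor levels but holding no voxels yields NA with a warning.
#' @export
roi_means <- function(map, labels) {
  if (!identical(dim(map), dim(labels)))
    stop("map and labels must share a grid")
  keep <- !is.na(labels) & labels != 0
  lv <- sort(unique(labels[keep]))
  out <- vapply(lv, function(l) {
    v <- map[keep & labels == l]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning("label ", l, " has no usable voxels")
      return(NA_real_)
    }
    mean(v)
  }, numeric(1))
  names(out) <- lv
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, applied within one
#' family of tests (one family per MRI metric, across regions).
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param alpha significance level on the adjusted values (default 0.05).
#' @return list with `p_adjusted` and logical `reject` (`p_adjusted < alpha`);
#'   empty input yields empty output.
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(list(p_adjusted = numeric(0), reject = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj < alpha)
}

check_table <- function(table, need_nfl = FALSE) {
  need <- c("subject_id", "roi", "age", "sex")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table is missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(table$age) || anyNA(table$sex))
    stop("age and sex must not be missing")
  if (need_nfl && is.null(table$nfl))
    stop("table has no nfl column")
  invisible(table)
}

#' Quadratic age regression per region
#'
#' For each region, ordinary least squares of the regional mean metric on
#' mean-centred age, centred age squared and sex (no interactions).  P-values
#' of each coefficient are FDR-adjusted across regions.  When the quadratic
#' coefficient is negative the age of apparent maximum,
#' `mean_age - beta_age / (2 * beta_age2)`, is reported; otherwise it is NA.
#'
#' @param table data frame with columns `subject_id`, `roi`, `age`, `sex`
#'   and `mean_ndi` / `mean_odi` (one row per subject x ROI).
#' @param metric `"ndi"` or `"odi"`.
#' @param alpha significance level applied to the adjusted p-values.
#' @return data frame with one row per ROI: coefficients, raw and adjusted
#'   p-values, rejection flags and `peak_age`.  Sex is coded 0/1 as supplied.
#' @export
quadratic_age_fit <- function(table, metric = c("ndi", "odi"), alpha = 0.05) {
  metric <- match.arg(metric)
  check_table(table)
  ycol <- paste0("mean_", metric)
  if (is.null(table[[ycol]])) stop("table has no column ", ycol)
  rois <- unique(table$roi)
  mean_age <- mean(table$age[!duplicated(table$subject_id)])
  rows <- lapply(rois, function(r) {
    d <- table[table$roi == r, ]
    if (nrow(d) < 10) stop("fewer than 10 subjects for ROI ", r)
    d$age_c <- d$age - mean_age
    X <- cbind(1, d$age_c, d$age_c^2, d$sex)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      culprit <- c("intercept", "age", "age2", "sex")[setdiff(seq_len(ncol(X)),
                                                              qrX$pivot[seq_len(qrX$rank)])]
      stop("rank-deficient design for ROI ", r, "; collinear column(s): ",
           paste(culprit, collapse = ", "))
    }
    fit <- lm(d[[ycol]] ~ age_c + I(age_c^2) + sex, data = d)
    sm <- summary(fit)$coefficients
    data.frame(roi = r,
               intercept = sm[1, 1], beta_age = sm[2, 1],
               beta_age2 = sm[3, 1], beta_sex = sm[4, 1],
               p_age = sm[2, 4], p_age2 = sm[3, 4], p_sex = sm[4, 4],
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  for (cf in c("age", "age2", "sex")) {
    adj <- fdr_adjust(rep[[paste0("p_", cf)]], alpha)
    rep[[paste0("p_", cf, "_fdr")]] <- adj$p_adjusted
    rep[[paste0("sig_", cf)]] <- adj$reject
  }
  rep$peak_age <- ifelse(rep$beta_age2 < 0,
                         mean_age - rep$beta_age / (2 * rep$beta_age2),
                         NA_real_)
  attr(rep, "mean_age") <- mean_age
  rownames(rep) <- NULL
  rep
}

#' Association between plasma NfL and regional NDI
#'
#' NfL values are log-transformed (natural log) to remove skewness; log-NfL
#' and NDI are then z-scored over the included sample and log-NfL is
#' regressed on z-NDI with age and sex as covariates.  Subjects with
#' non-positive or missing NfL are excluded with a warning.
#'
#' @param table cohort table as in [quadratic_age_fit()], with an `nfl`
#'   column in pg/mL.
#' @param roi name of the region whose NDI to use.
#' @return list with `beta_ndi`, `p_ndi`, the full coefficient matrix
#'   (`coefficients`), and `n` (subjects included).
#' @export
nfl_association <- function(table, roi) {
  check_table(table, need_nfl = TRUE)
  d <- table[table$roi == roi, ]
  if (nrow(d) == 0) stop("no rows for ROI ", roi)
  bad <- is.na(d$nfl) | d$nfl <= 0
  if (any(bad)) {
    warning(sum(bad), " subject(s) excluded for non-positive or missing NfL")
    d <- d[!bad, ]
  }
  z <- function(x) (x - mean(x)) / sd(x)
  d$z_nfl <- z(log(d$nfl))
  d$z_ndi <- z(d$mean_ndi)
  fit <- lm(z_nfl ~ z_ndi + age + sex, data = d)
  sm <- summary(fit)$coefficients
  list(beta_ndi = sm["z_ndi", 1], p_ndi = sm["z_ndi", 4],
       coefficients = sm, n = nrow(d))
}
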