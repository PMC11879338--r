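#' Read an externally deposited synthetic ECG database (schema-sniffing)
#'
#' Adapter for pathway-swept ECG deposits whose on-disk layout is not
#' known ahead of time. The adapter inspects the file or directory and
#' tries, in order: the package's own container ([readDatabase()]); a
#' directory holding a parameter table (`*.csv` or `*.parquet` with
#' columns recognisably containing rho/z/phi/tven and a ventricle label)
#' plus a signal table; or a single CSV parameter table without signals
#' (parameters only). Anything else raises an informative error listing
#' what was found.
#'
#' @param path file or directory of the deposit.
#' @return an [ECGDatabase-class] object (signals may be a 0-length
#'   array when the deposit contains only parameters).
#' @export
readZenodoDatabase <- function(path) {
  if (!file.exists(path))
    stop("deposit not found: ", path, call. = FALSE)
  if (dir.exists(path) &&
      file.exists(file.path(path, "meta.json")))
    return(readDatabase(path))

  files <- if (dir.exists(path))
    list.files(path, full.names = TRUE) else path
  tabs <- files[grepl("\\.(csv|parquet)$", files, ignore.case = TRUE)]
  readTab <- function(f)
    if (grepl("parquet$", f, ignore.case = TRUE))
      as.data.frame(arrow::read_parquet(f)) else
      utils::read.csv(f, stringsAsFactors = FALSE)
  normalize <- function(df) {
    names(df) <- tolower(names(df))
    aliases <- list(rho = c("rho", "r"), z = c("z", "apicobasal"),
                    phi = c("phi", "rotational"),
                    tven = c("tven", "t_ven", "tv"),
                    ventricle = c("ventricle", "side", "chamber"))
    out <- list()
    for (nm in names(aliases)) {
      hit <- intersect(aliases[[nm]], names(df))
      if (length(hit)) out[[nm]] <- df[[hit[1]]]
    }
    if (length(out) < length(aliases)) return(NULL)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  for (f in tabs) {
    df <- tryCatch(readTab(f), error = function(e) NULL)
    if (is.null(df)) next
    par <- normalize(df)
    if (is.null(par)) next
    n <- nrow(par)
    par$beat <- seq_len(n)
    par$valid <- TRUE
    for (col in c("alpha", "gamma", "beta", "cvap", "d", "tatria",
                  "tEarliestVent", "tLatestVent"))
      if (is.null(par[[col]])) par[[col]] <- NA_real_
    par$region <- bullseyeRegion(par$ventricle, par$z, par$phi)
    sigFile <- setdiff(tabs, f)
    signals <- array(0, c(n, 12, 0))
    if (length(sigFile)) {
      sg <- tryCatch(readTab(sigFile[1]), error = function(e) NULL)
      num <- sg[vapply(sg, is.numeric, logical(1))]
      if (!is.null(sg) && nrow(sg) == n * 12)
        signals <- aperm(array(as.matrix(num), c(12, n, ncol(num))),
                         c(2, 1, 3))
    }
    dimnames(signals) <- list(NULL, leadNames12, NULL)
    return(new("ECGDatabase", params = par, signals = signals,
               period = 1, meta = list(schema = "external-deposit",
                                       source = path)))
  }
  stop("unrecognised deposit layout at ", path, "; found: ",
       paste(basename(files), collapse = ", "),
       ". Expected a parameter table (csv/parquet) with rho/z/phi/tven ",
       "and ventricle columns.", call. = FALSE)
}
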