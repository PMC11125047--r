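# Optional adapter for the WESAD dataset's native per-subject bundles.
#
# The public dataset ships one Python-pickled file per subject (SX/SX.pkl)
# holding wrist and chest streams plus a 700 Hz label track. R cannot read
# pickles natively, so the adapter shells out to a Python interpreter (if one
# is on the PATH) to dump the wrist channels and labels to CSV, then builds a
# `raw_session` from them. The study protocol labels used are: 1 baseline
# (neutral), 2 stress, 3 amusement; everything else is dropped.

wesad_py <- '
import pickle, sys, os, csv
path, out = sys.argv[1], sys.argv[2]
with open(path, "rb") as fh:
    d = pickle.load(fh, encoding="latin1")
w = d["signal"]["wrist"]
os.makedirs(out, exist_ok=True)
rates = {"ACC": 32, "BVP": 64, "EDA": 4, "TEMP": 4}
for key, arr in (("ACC", w["ACC"]), ("BVP", w["BVP"]), ("EDA", w["EDA"]),
                 ("TEMP", w["TEMP"])):
    cols = arr.shape[1] if arr.ndim > 1 else 1
    names = ["%s_%s" % (key, ax) for ax in "xyz"][:cols] if key == "ACC" else [key]
    for j, nm in enumerate(names):
        with open(os.path.join(out, nm + ".csv"), "w", newline="") as fh:
            wtr = csv.writer(fh); wtr.writerow(["value"])
            col = arr[:, j] if arr.ndim > 1 else arr
            for v in col: wtr.writerow([float(v)])
lab = d["label"]
with open(os.path.join(out, "label700.csv"), "w", newline="") as fh:
    wtr = csv.writer(fh); wtr.writerow(["label"])
    for v in lab: wtr.writerow([int(v)])
'

#' Read one native WESAD subject bundle (optional adapter)
#'
#' Converts the subject's pickled bundle to CSV via a Python interpreter and
#' assembles a `raw_session` of the six wrist channels with a per-second
#' 3-state label track (protocol codes: baseline -> 0, stress -> 1,
#' amusement -> 2; other protocol phases are dropped, truncating the session
#' to the labeled study segments in time order).
#'
#' @param pkl_path Path to `SX.pkl`.
#' @param python Python executable to use.
#' @return A `raw_session` restricted to seconds labeled neutral, stress or
#'   amusement.
#' @export
read_wesad_subject <- function(pkl_path, python = "python") {
  if (Sys.which(python) == "")
    stop("no python interpreter found for the pickle conversion",
         call. = FALSE)
  out <- tempfile("wesad")
  script <- tempfile(fileext = ".py")
  writeLines(wesad_py, script)
  status <- system2(python, c(script, shQuote(pkl_path), shQuote(out)))
  if (status != 0) stop("pickle conversion failed", call. = FALSE)
  rates <- c(ACC_x = 32, ACC_y = 32, ACC_z = 32, BVP = 64, EDA = 4, TEMP = 4)
  lab700 <- utils::read.csv(file.path(out, "label700.csv"))$label
  T <- length(lab700) %/% 700L
  # per-second label = mode of the 700 Hz codes within the second
  lab_s <- vapply(seq_len(T), function(t) {
    chunk <- lab700[(t - 1L) * 700L + seq_len(700L)]
    as.integer(names(which.max(table(chunk))))
  }, 0L)
  keep <- which(lab_s %in% 1:3)
  lab3 <- c(`1` = 0L, `2` = 1L, `3` = 2L)[as.character(lab_s[keep])]
  sig <- lapply(names(rates), function(s) {
    v <- utils::read.csv(file.path(out, paste0(s, ".csv")))$value
    fs <- rates[[s]]
    idx <- unlist(lapply(keep, function(t) (t - 1L) * fs + seq_len(fs)))
    list(rate = fs, values = v[idx[idx <= length(v)]])
  })
  names(sig) <- names(rates)
  structure(list(subject_id = sub("\\.pkl$", "", basename(pkl_path)),
                 signals = sig, labels = unname(lab3)),
            class = "raw_session")
}
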