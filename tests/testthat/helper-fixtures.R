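# Shared fixture builders (all generated in code, no binary data).

# quick FeatureSet: ab is features x samples; groups/types recycled
makeFset <- function(ab, mz, rt, groups, types = NULL, inj = NULL,
                     filled = NULL, names = NULL) {
  nS <- ncol(ab)
  if (is.null(types)) types <- rep("incubation", nS)
  if (is.null(inj)) inj <- seq_len(nS)
  if (is.null(names)) names <- featureName(mz, rt)
  colnames(ab) <- paste0("S", seq_len(nS))
  fd <- data.frame(mz = mz, rt = rt, rt_lo = rt - 10, rt_hi = rt + 10,
                   name = names)
  rownames(ab) <- make.unique(names)
  cd <- data.frame(sample_id = colnames(ab), group = groups,
                   sample_type = types, injection_index = inj,
                   polarity = "pos")
  FeatureSet(ab, featureData = fd, sampleData = cd, filled = filled)
}

# an EIC object holding a clean Gaussian peak (area = `area`)
makeGaussianEIC <- function(mz = 218.1539, apex = 100, sigma = 4,
                            area = 1e6, interval = 0.5,
                            rt_range = c(60, 140)) {
  rts <- seq(rt_range[1], rt_range[2], by = interval)
  y <- area * dnorm(rts, apex, sigma)
  keep <- y > 1e-6
  structure(list(mz = mz,
                 points = data.frame(scan = round(rts[keep] / interval),
                                     rt = rts[keep], mz = mz,
                                     intensity = y[keep])),
            class = "EIC")
}

# a noise-free scenario: one parent-like compound only
noiseFreeScenario <- function(compounds = NULL) {
  sc <- smallScenario()
  sc$n_background <- 0
  sc$drift_rate <- 0
  sc$noise <- list(density = 0, meanlog = log(500), sdlog = 1,
                   sigma_ppm = 0, intensity_cv = 0,
                   bleed_area = 0, bleed_sdlog = 0.5)
  if (!is.null(compounds)) sc$species <- compounds
  sc
}

# minimal single-spectrum-list mzML document (text, arrays built in code)
makeMzML <- function(path, scans, compress = FALSE, profile = FALSE) {
  enc <- function(x, compress) {
    raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
    if (compress) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  comp <- if (compress)
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  mode <- if (profile)
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>'
  spec <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '%s',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitName="second"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>%s',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>%s',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(s$mz), mode, s$rt, comp, enc(s$mz, compress),
      comp, enc(s$intensity, compress))
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="r1"><spectrumList count="', length(scans), '">',
    paste(spec, collapse = ""), '</spectrumList></run></mzML>')
  writeLines(doc, path)
  path
}
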