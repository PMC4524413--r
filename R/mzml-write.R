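# Minimal mzML 1.1.0 writer.
#
# Emits non-indexed mzML with uncompressed 64-bit little-endian binary
# arrays, per-spectrum polarity and spectrum-representation terms, and scan
# start times in seconds.  Output is deterministic: equal samples produce
# byte-identical files.

b64_doubles <- function(x) {
  if (length(x) == 0L) return("")
  gsub("[\r\n]", "", jsonlite::base64_enc(
    writeBin(as.numeric(x), raw(), size = 8L, endian = "little")))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

mzml_spectrum_xml <- function(s, index) {
  polarity <- switch(s$ion_mode,
    positive = '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
    negative = '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>',
    "")
  repr <- if (s$centroided) {
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  }
  spec_type <- if (s$ms_level == 1L) {
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
  }
  precursor <- if (s$ms_level > 1L) {
    sprintf(paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
      'name="selected ion m/z" value="%.10g" unitCvRef="MS" ',
      'unitAccession="MS:1000040" unitName="m/z"/></selectedIon>',
      '</selectedIonList></precursor></precursorList>'), s$precursor_mz)
  } else ""
  mz_b64 <- b64_doubles(s$mz)
  it_b64 <- b64_doubles(s$intensity)
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
            index, s$index + 1L, length(s$mz)),
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
            s$ms_level),
    spec_type, polarity, repr,
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    sprintf(paste0('<scan><cvParam cvRef="MS" accession="MS:1000016" ',
                   'name="scan start time" value="%.10g" unitCvRef="UO" ',
                   'unitAccession="UO:0000010" unitName="second"/></scan>'),
            s$rt),
    '</scanList>', precursor,
    '<binaryDataArrayList count="2">',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(mz_b64)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<binary>', mz_b64, '</binary></binaryDataArray>',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(it_b64)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<binary>', it_b64, '</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'
  )
}

#' Write a sample as mzML 1.1.0
#'
#' Writes a minimal, standard-conformant mzML document: non-indexed,
#' uncompressed 64-bit float arrays, spectrum-level polarity and
#' representation (centroid/profile) terms, scan start times in seconds.
#' The output is deterministic, so equal samples yield byte-identical
#' files.
#'
#' @param sample an [lcms_sample()] object
#' @param path output file path (conventionally `.mzML`)
#' @return `path`, invisibly
#' @export
write_mzml <- function(sample, path) {
  stopifnot(inherits(sample, "lcms_sample"))
  n <- length(sample$scans)
  header <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="',
    xml_escape(sample$id), '">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="lcmspipe"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="', xml_escape(sample$id),
    '" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="DP1">\n', n)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (i in seq_len(n)) {
    writeChar(paste0(mzml_spectrum_xml(sample$scans[[i]], i - 1L), "\n"),
              con, eos = NULL)
  }
  writeChar('</spectrumList>\n</run>\n</mzML>\n', con, eos = NULL)
  invisible(path)
}
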