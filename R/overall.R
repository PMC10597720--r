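# Combination of per-eye BCVA-change and corneal grades into per-eye and
# overall KVA grades: the most severe finding across the two components of
# both eyes (with "NA" ranking as 0 but preserved for display).

#' Combine component grades into the overall KVA grade
#'
#' Per eye, the KVA grade is the more severe of the BCVA-change grade and
#' the corneal-examination grade; the overall KVA grade is that of the more
#' severely affected eye. \code{"NA"} (stable/improved vision) ranks as 0
#' in the combination but is kept distinct in the per-component fields.
#'
#' @param od_bcva,os_bcva BCVA-change grade labels for right (OD) and left
#'   (OS) eye.
#' @param od_corneal,os_corneal corneal-exam grade labels per eye.
#' @return a \code{kva_overall} list with \code{od} and \code{os}
#'   assessments (each \code{bcva_grade}, \code{corneal_grade},
#'   \code{eye_kva}) and \code{overall_kva}.
#' @export
#' @examples
#' compute_overall("1", "NA", "0", "2")$overall_kva  # "2"
compute_overall <- function(od_bcva, os_bcva, od_corneal, os_corneal) {
  eye_block <- function(eye, bcva, corneal) {
    list(eye = eye, bcva_grade = bcva, corneal_grade = corneal,
         eye_kva = grade_max(bcva, corneal))
  }
  od <- eye_block("OD", od_bcva, od_corneal)
  os <- eye_block("OS", os_bcva, os_corneal)
  structure(list(od = od, os = os,
                 overall_kva = grade_max(od$eye_kva, os$eye_kva)),
            class = "kva_overall")
}
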