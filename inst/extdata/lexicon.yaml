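# Synthetic stand-in lexicon for the ten-category breast-MRI structured
# report template. Terms are standard BI-RADS descriptor vocabulary; the
# definitions are short paraphrases written for this package. Substitute a
# file with the same layout to use the full fifth-edition MRI lexicon.
amount_of_fibroglandular_tissue:
  definition: Overall proportion of fibroglandular tissue in the breast, from almost entirely fat to extreme.
  terms:
    - almost entirely fat
    - scattered fibroglandular tissue
    - heterogeneous fibroglandular tissue
    - extreme fibroglandular tissue
background_parenchymal_enhancement:
  definition: Degree of normal parenchymal enhancement after contrast, graded minimal to marked.
  terms:
    - minimal background enhancement
    - mild background enhancement
    - moderate background enhancement
    - marked background enhancement
mass_non_mass:
  definition: Space-occupying lesion (shape and margin) or non-mass enhancement pattern.
  terms:
    - oval circumscribed mass
    - round mass
    - irregular mass
    - spiculated mass
    - non-mass enhancement
axillary_lymph_nodes:
  definition: Appearance of axillary nodes, from normal to morphologically suspicious.
  terms:
    - normal axillary nodes
    - enlarged axillary nodes
    - suspicious axillary nodes
skin_lesions:
  definition: Skin involvement such as thickening or retraction.
  terms:
    - no skin lesion
    - skin thickening
    - skin retraction
non_enhancing_findings:
  definition: Findings without contrast enhancement, e.g. cysts or duct ectasia.
  terms:
    - simple cyst
    - non-enhancing focus
    - duct ectasia
associated_findings:
  definition: Secondary findings accompanying a lesion, e.g. distortion or edema.
  terms:
    - no associated findings
    - architectural distortion
    - nipple retraction
    - peritumoral edema
fat_containing_lesions:
  definition: Lesions containing macroscopic fat.
  terms:
    - intramammary lymph node
    - hamartoma
    - fat necrosis
dce_curve_assessment:
  definition: Dynamic contrast-enhanced kinetic curve type; washout kinetics lean malignant.
  terms:
    - persistent enhancement curve
    - plateau enhancement curve
    - washout enhancement curve
prosthesis:
  definition: Presence and integrity of breast implants.
  terms:
    - no implant
    - intact silicone implant
    - peri-implant fluid
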