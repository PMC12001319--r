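# Style-transform presets. Each style is an ordered operator pipeline applied
# to the anatomical target of a structure set. Depths are in mm on the phantom
# scale; radii are in voxels. Styles marked held_out are reserved for
# evaluation and never drawn during meta-training.
styles:
  # -- training styles: target-vs-neighbour family ---------------------------
  - name: dilate2
    steps:
      - op: dilate
        radius_px: 2
  - name: erode2
    steps:
      - op: erode
        radius_px: 2
  - name: exclude_sup
    steps:
      - op: cap_extension_into
        ref: neighbor_sup
        depth_mm: 0
  - name: into_sup_9mm
    steps:
      - op: extend_into
        ref: neighbor_sup
        depth_mm: 9
  - name: into_post_6mm
    steps:
      - op: extend_into
        ref: neighbor_post
        depth_mm: 6
  - name: with_sup_and_post
    steps:
      - op: keep_slices_with
        ref: neighbor_sup
      - op: keep_slices_with
        ref: neighbor_post
  # -- training styles: reference-structure family ---------------------------
  - name: dilate1
    steps:
      - op: dilate
        radius_px: 1
  - name: erode1
    steps:
      - op: erode
        radius_px: 1
  - name: with_ref_a
    steps:
      - op: keep_slices_with
        ref: ref_a
  - name: with_ref_b
    steps:
      - op: keep_slices_with
        ref: ref_b
  - name: without_refs
    steps:
      - op: keep_slices_without
        ref: [ref_a, ref_b]
  # -- training styles: mixed family -----------------------------------------
  - name: dilate3
    steps:
      - op: dilate
        radius_px: 3
  - name: erode3
    steps:
      - op: erode
        radius_px: 3
  - name: with_sup
    steps:
      - op: keep_slices_with
        ref: neighbor_sup
  - name: with_post
    steps:
      - op: keep_slices_with
        ref: neighbor_post
  - name: without_neighbors
    steps:
      - op: keep_slices_without
        ref: [neighbor_sup, neighbor_post]
  # -- held-out evaluation styles --------------------------------------------
  - name: cap_sup_3mm
    held_out: true
    steps:
      - op: cap_extension_into
        ref: neighbor_sup
        depth_mm: 3
  - name: into_post_9mm
    held_out: true
    steps:
      - op: extend_into
        ref: neighbor_post
        depth_mm: 9
  - name: exclude_ref_b
    held_out: true
    steps:
      - op: exclude_structure
        ref: ref_b
  - name: superior_half
    held_out: true
    steps:
      - op: aspect_split
        axis: superior
        keep_fraction: 0.5
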