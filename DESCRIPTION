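Package: weedseg
Title: Crop and Weed Semantic Segmentation with Mobile Dense Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-pixel crop/weed/soil segmentation of row-crop field
    imagery on a CPU budget. Implements a width-multiplier channel schedule with
    a multiples-of-8 variant, a shape-checked convolutional computation graph
    with multiply-accumulate (MAC) cost auditing, depthwise-separable
    DenseNet-Mobile blocks in a naive and a depthwise-cached form, a stationary
    U-Net teacher and a mobile U-Net/MobileNets/DenseNet hybrid student,
    ensemble averaging of class-probability maps, knowledge distillation from
    soft teacher labels, Dice-based segmentation error metrics, and a seeded
    synthetic field-image generator with exact ground truth so the whole
    pipeline runs end-to-end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
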