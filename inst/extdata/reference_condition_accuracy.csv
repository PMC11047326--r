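model,lighting,condition,accuracy
ResSTN,natural,full_body,95.23
ResSTN,natural,cropped,90.85
ResSTN,natural,occluded,94.02
ResSTN,artificial,full_body,94.86
ResSTN,artificial,cropped,90.02
ResSTN,artificial,occluded,93.87
ResSTN-NE,natural,full_body,94.47
ResSTN-NE,natural,cropped,88.24
ResSTN-NE,natural,occluded,92.11
ResSTN-NE,artificial,full_body,93.20
ResSTN-NE,artificial,cropped,88.04
ResSTN-NE,artificial,occluded,91.61
ResNet101-NE,natural,full_body,91.35
ResNet101-NE,natural,cropped,85.82
ResNet101-NE,natural,occluded,90.25
ResNet101-NE,artificial,full_body,89.38
ResNet101-NE,artificial,cropped,85.32
ResNet101-NE,artificial,occluded,87.66
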