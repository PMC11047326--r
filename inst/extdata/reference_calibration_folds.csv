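metric,fold,threshold,accuracy
euclidean,1,2.45,94.85
euclidean,2,2.45,94.92
euclidean,3,2.45,94.85
euclidean,4,2.45,96.41
euclidean,5,2.45,92.84
euclidean,6,2.45,92.82
euclidean,7,2.45,88.91
euclidean,8,2.45,89.29
euclidean,9,2.45,91.54
euclidean,10,2.45,92.55
cosine,1,0.0047,96.89
cosine,2,0.0047,95.95
cosine,3,0.0047,94.89
cosine,4,0.0047,97.88
cosine,5,0.0047,94.75
cosine,6,0.0047,94.85
cosine,7,0.0047,89.72
cosine,8,0.0047,91.68
cosine,9,0.0047,93.66
cosine,10,0.0047,95.56
mahalanobis,1,4.24,94.85
mahalanobis,2,4.24,94.92
mahalanobis,3,4.24,94.85
mahalanobis,4,4.24,96.41
mahalanobis,5,4.24,92.84
mahalanobis,6,4.24,92.82
mahalanobis,7,4.24,88.91
mahalanobis,8,4.24,89.29
mahalanobis,9,4.24,91.54
mahalanobis,10,4.24,92.55
manhattan,1,72.2,93.21
manhattan,2,72.2,93.54
manhattan,3,72.2,93.32
manhattan,4,72.2,96.70
manhattan,5,72.2,94.68
manhattan,6,72.2,93.58
manhattan,7,72.2,90.27
manhattan,8,72.2,91.59
manhattan,9,72.2,93.12
manhattan,10,72.2,94.63
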