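G0015 pp G0016
G0016 pp G0017
G0017 pp G0018
G0018 pp G0019
G0019 pp G0020
G0020 pp G0021
G0021 pp G0022
G0022 pp G0023
G0023 pp G0024
G0024 pp G0025
G0025 pp G0026
G0026 pp G0027
G0027 pp G0028
G0028 pp G0029
G0029 pp G0030
G0030 pp G0015
G0015 pp G0022
G0018 pp G0026
G0001 pp G0015
G0001 pp G0013
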