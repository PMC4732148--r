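# Example dataset manifest for the delimited sensor dialect.
#
# This layout mirrors a public 113-channel body-worn benchmark: each
# recording file has one row per time step at 30 Hz, whitespace-separated,
# with sensor channels in fixed columns, NaN for missing samples, and an
# integer activity label column. Column indices are 1-based and the same
# selection applies to every file listed. Recording paths are relative to
# this manifest. Roles: train / validation / test (repeatable).
#
# label_column  = index of the label column
# channels      = channel columns, comma-separated indices or a:b ranges
# modality_tags = one tag per selected channel (acc/gyro/mag/...)

label_column = 16
channels = 1:15
sample_rate = 30
modality_tags = acc,acc,acc,acc,acc,gyro,gyro,gyro,gyro,gyro,mag,mag,mag,mag,mag
train = train.txt
validation = validation.txt
test = test.txt
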